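#' Prior specification for rate parameters
#'
#' Rates get a gamma prior with mean \code{m} and variance \code{v}
#' (shape \eqn{m^2/v}, rate \eqn{m/v}); the hyperparameters themselves get
#' uniform(0, 1\] hyperpriors and are sampled in the chain unless
#' \code{update_hyper = FALSE}.
#'
#' @param m0,v0 Initial gamma mean and variance, in (0, 1].
#' @param update_hyper Sample \code{m} and \code{v}?
#' @return An object of class \code{chrom_prior}.
#' @export
prior_spec <- function(m0 = 0.5, v0 = 0.25, update_hyper = TRUE) {
  stopifnot(m0 > 0, m0 <= 1, v0 > 0, v0 <= 1)
  structure(list(m0 = m0, v0 = v0, update_hyper = update_hyper),
            class = "chrom_prior")
}

gamma_shape <- function(m, v) m^2 / v
gamma_rate <- function(m, v) m / v

log_rate_prior <- function(rates, m, v) {
  if (length(rates) == 0L) return(0)
  # rates are kept off exact zero; the density at the smallest double is
  # still finite for shape < 1
  sum(stats::dgamma(pmax(rates, .Machine$double.xmin),
                    shape = gamma_shape(m, v),
                    rate = gamma_rate(m, v), log = TRUE))
}

# gamma prior draw with exact-zero underflow (shape << 1) nudged to the
# smallest positive double so densities and logs stay finite
rgamma_pos <- function(n, m, v) {
  pmax(stats::rgamma(n, gamma_shape(m, v), gamma_rate(m, v)),
       .Machine$double.xmin)
}

# reflecting uniform random-walk proposal inside (lo, hi]
reflect <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

# autocorrelation-time effective sample size (initial positive sequence)
ess <- function(x) {
  n <- length(x)
  if (n < 10L || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  s <- 0
  for (r in ac) {
    if (r < 0.05) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

mcmc_likelihood_fun <- function(tree, counts, spec, space, root_prior) {
  force(tree); force(counts)
  function(params) {
    m <- suppressWarnings(build_q(spec, params, space, root_prior = root_prior))
    ll <- tryCatch(tree_log_likelihood(tree, counts, m),
                   error = function(e) -Inf)
    if (!is.finite(ll)) -Inf else ll
  }
}

#' Fixed-model Bayesian MCMC for chromosome-number models
#'
#' Metropolis-Hastings over the model's rates (log-scale random walk mixed
#' with independence draws from the gamma prior) and, optionally, the gamma
#' hyperparameters (reflecting uniform walk in (0, 1\]). Proposal scales are
#' tuned during burn-in only. Supported families are those whose free
#' parameters are all nonnegative rates (constant-rate dysploidy families,
#' ordered ladder, full Mk); the linear-rate families are rejected because
#' the gamma prior has no support for signed coefficients.
#'
#' @param tree Rooted \code{phylo} with branch lengths.
#' @param counts Named integer vector of haploid counts.
#' @param spec A \code{chrom_model_spec}.
#' @param prior A \code{chrom_prior}.
#' @param iterations,burnin,thin Chain control; samples are recorded every
#'   \code{thin} iterations after \code{burnin}.
#' @param seed Integer seed; chains are reproducible.
#' @param space Optional \code{chrom_space}.
#' @param root_prior Passed to \code{build_q}.
#' @param ess_floor Warn when any parameter's effective sample size falls
#'   below this (default 100).
#' @return A \code{chrom_mcmc}: \code{samples} data frame (iteration, rates,
#'   \code{m}, \code{v}, \code{logL}), acceptance rates and per-parameter ESS.
#' @export
mcmc_fixed <- function(tree, counts, spec, prior = prior_spec(),
                       iterations = 2e4L, burnin = iterations %/% 10L,
                       thin = 10L, seed = 1L, space = NULL,
                       root_prior = "uniform_nonzero", ess_floor = 100) {
  stopifnot(iterations > burnin, thin >= 1L)
  counts <- check_counts(counts, tree)
  if (is.null(space)) space <- chrom_state_space(counts)
  pnames <- family_param_names(spec$family, space, spec$rate_classes)
  if (any(grepl("_lin$", pnames))) {
    stop("mcmc_fixed supports rate-only families (no linear coefficients)")
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(as.integer(seed))

  loglik <- mcmc_likelihood_fun(tree, counts, spec, space, root_prior)
  k <- length(pnames)
  m <- prior$m0; v <- prior$v0
  theta <- stats::setNames(rgamma_pos(k, m, v), pnames)
  ll <- loglik(theta)
  lp <- log_rate_prior(theta, m, v)
  sd_rw <- 0.8; sd_hyp <- 0.2
  acc <- c(rate = 0, hyper = 0); prop <- c(rate = 0, hyper = 0)
  n_keep <- (iterations - burnin) %/% thin
  samples <- matrix(NA_real_, n_keep, k + 4L,
                    dimnames = list(NULL, c("iteration", pnames, "m", "v", "logL")))
  kept <- 0L
  for (it in seq_len(iterations)) {
    if (stats::runif(1L) < 0.7 || !prior$update_hyper) {
      # rate update
      j <- sample.int(k, 1L)
      prop["rate"] <- prop["rate"] + 1
      if (stats::runif(1L) < 0.5) {
        th_new <- theta
        th_new[j] <- theta[j] * exp(stats::rnorm(1L, 0, sd_rw))
        lr <- log(th_new[j] / theta[j])   # log-walk Jacobian
        ll_new <- loglik(th_new)
        lp_new <- log_rate_prior(th_new, m, v)
        if (is.finite(ll_new) &&
            log(stats::runif(1L)) < ll_new - ll + lp_new - lp + lr) {
          theta <- th_new; ll <- ll_new; lp <- lp_new
          acc["rate"] <- acc["rate"] + 1
        }
      } else {
        # independence draw from the prior: prior cancels proposal
        th_new <- theta
        th_new[j] <- rgamma_pos(1L, m, v)
        ll_new <- loglik(th_new)
        if (is.finite(ll_new) && log(stats::runif(1L)) < ll_new - ll) {
          theta <- th_new; ll <- ll_new; lp <- log_rate_prior(theta, m, v)
          acc["rate"] <- acc["rate"] + 1
        }
      }
    } else {
      # hyperparameter update (uniform(0,1] hyperprior cancels)
      prop["hyper"] <- prop["hyper"] + 1
      m_new <- reflect(m + stats::rnorm(1L, 0, sd_hyp), 0, 1)
      v_new <- reflect(v + stats::rnorm(1L, 0, sd_hyp), 0, 1)
      if (m_new > 0 && v_new > 0) {
        lp_new <- log_rate_prior(theta, m_new, v_new)
        if (log(stats::runif(1L)) < lp_new - lp) {
          m <- m_new; v <- v_new; lp <- lp_new
          acc["hyper"] <- acc["hyper"] + 1
        }
      }
    }
    if (it <= burnin && it %% 200L == 0L && prop["rate"] > 0) {
      r <- acc["rate"] / prop["rate"]
      sd_rw <- min(5, max(0.05, sd_rw * exp(r - 0.3)))
    }
    if (it > burnin && (it - burnin) %% thin == 0L && kept < n_keep) {
      kept <- kept + 1L
      samples[kept, ] <- c(it, theta, m, v, ll)
    }
  }
  samples <- as.data.frame(samples[seq_len(kept), , drop = FALSE])
  ess_vals <- vapply(c(pnames, "m", "v"), function(nm) ess(samples[[nm]]), 0)
  if (any(ess_vals < ess_floor)) {
    warning("effective sample size below ", ess_floor, " for: ",
            paste(names(ess_vals)[ess_vals < ess_floor], collapse = ", "))
  }
  structure(list(samples = samples,
                 acceptance = ifelse(prop > 0, acc / prop, NA_real_),
                 ess = ess_vals, spec = spec, prior = prior,
                 seed = seed, thin = thin, burnin = burnin),
            class = "chrom_mcmc")
}

# canonical key of an RJ configuration: zero set, then partition blocks
# labelled in order of first appearance
rj_config_key <- function(z) {
  zero <- which(z == 0L)
  nz <- z[z != 0L]
  relab <- match(z, unique(nz))
  relab[z == 0L] <- 0L
  paste(relab, collapse = ".")
}

# number of single-rate reassignment destinations from configuration z
rj_n_dest <- function(z, r) {
  cur <- z[r]
  blocks <- setdiff(unique(z), c(0L, cur))
  n <- length(blocks)                 # other nonzero blocks
  if (cur != 0L) n <- n + 1L          # the zero block
  alone <- sum(z == cur) == 1L
  if (!(alone && cur != 0L)) n <- n + 1L  # brand-new singleton block
  n
}

# enumerate destinations; each is list(z = new assignment, birth = TRUE/FALSE)
rj_destinations <- function(z, r) {
  cur <- z[r]
  out <- list()
  for (b in setdiff(unique(z), c(0L, cur))) {
    z2 <- z; z2[r] <- b
    out[[length(out) + 1L]] <- list(z = z2, birth = FALSE)
  }
  if (cur != 0L) {
    z2 <- z; z2[r] <- 0L
    out[[length(out) + 1L]] <- list(z = z2, birth = FALSE)
  }
  alone <- sum(z == cur) == 1L
  if (!(alone && cur != 0L)) {
    z2 <- z; z2[r] <- max(z) + 1L
    out[[length(out) + 1L]] <- list(z = z2, birth = TRUE)
  }
  out
}

#' Reversible-jump MCMC over rate-class partitions
#'
#' Samples the posterior over full-Mk models on the observed chromosome-count
#' ladder that differ in how the \eqn{n(n-1)} directed rates are grouped into
#' rate classes, including a distinguished zero class of rates pinned at 0.
#' The model prior is uniform over these augmented partitions. Trans-model
#' moves reassign one rate at a time (which merges classes when the last
#' member leaves, splits off singleton classes, and moves rates to or from
#' the zero class); new classes draw their rate from the gamma prior so the
#' dimension-matching factors cancel. Within-model moves update class rates
#' and hyperparameters as in \code{mcmc_fixed}.
#'
#' @inheritParams mcmc_fixed
#' @return A \code{chrom_rj}: \code{samples} (one row per retained sample:
#'   iteration, number of nonzero classes, number of zero rates, logL, the
#'   configuration key and class rates as a list column), \code{summary}
#'   (mean/range of nonzero class count and zero-rate count, per-rate zero
#'   proportions), acceptance rates and the rate-pair labels.
#' @export
rj_mcmc <- function(tree, counts, prior = prior_spec(),
                    iterations = 2e4L, burnin = iterations %/% 10L,
                    thin = 10L, seed = 1L, space = NULL,
                    root_prior = "uniform_nonzero") {
  counts <- check_counts(counts, tree)
  if (is.null(space)) space <- chrom_state_space(counts)
  pairs <- full_mk_pairs(space)
  n_rates <- nrow(pairs)
  rate_labels <- paste0(pairs$from, "->", pairs$to)
  loglik <- function(z, theta) {
    spec <- chrom_model_spec("FULL_MK", rate_classes = z, space = space)
    m <- suppressWarnings(build_q(spec, theta, space, root_prior = root_prior))
    ll <- tryCatch(tree_log_likelihood(tree, counts, m), error = function(e) -Inf)
    if (is.finite(ll)) ll else -Inf
  }
  rj_sampler(loglik, n_rates, rate_labels, prior, iterations, burnin, thin, seed)
}

# the partition-and-rates kernel behind rj_mcmc, parameterized by an
# arbitrary log-likelihood function loglik(z, theta)
rj_sampler <- function(loglik, n_rates, rate_labels = paste0("r", seq_len(n_rates)),
                       prior = prior_spec(), iterations = 2e4L,
                       burnin = iterations %/% 10L, thin = 10L, seed = 1L) {
  stopifnot(iterations > burnin, thin >= 1L)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(as.integer(seed))
  m_h <- prior$m0; v_h <- prior$v0
  z <- rep(1L, n_rates)               # start: one shared class
  theta <- rgamma_pos(1L, m_h, v_h)
  ll <- loglik(z, theta)
  acc <- c(jump = 0, rate = 0, hyper = 0); prop <- acc
  sd_rw <- 0.8
  n_keep <- (iterations - burnin) %/% thin
  samp_it <- integer(n_keep); samp_classes <- integer(n_keep)
  samp_zero <- integer(n_keep); samp_ll <- numeric(n_keep)
  samp_key <- character(n_keep)
  samp_z <- vector("list", n_keep); samp_theta <- vector("list", n_keep)
  zero_hits <- numeric(n_rates)
  kept <- 0L
  for (it in seq_len(iterations)) {
    u <- stats::runif(1L)
    if (u < 0.5) {
      # trans-model: reassign one rate
      prop["jump"] <- prop["jump"] + 1
      r <- sample.int(n_rates, 1L)
      dests <- rj_destinations(z, r)
      if (length(dests)) {
        d <- dests[[sample.int(length(dests), 1L)]]
        z_new <- d$z
        theta_new <- theta
        if (d$birth) {
          theta_new[max(z_new)] <- rgamma_pos(1L, m_h, v_h)
        }
        # drop an emptied class and relabel compactly
        keep <- sort(setdiff(unique(z_new), 0L))
        relab <- match(z_new, keep); relab[z_new == 0L] <- 0L
        theta_new <- theta_new[keep]
        z_new <- relab
        ll_new <- loglik(z_new, theta_new)
        d_fwd <- length(dests)
        d_rev <- rj_n_dest(z_new, r)
        if (is.finite(ll_new) &&
            log(stats::runif(1L)) < ll_new - ll + log(d_fwd) - log(d_rev)) {
          z <- z_new; theta <- theta_new; ll <- ll_new
          acc["jump"] <- acc["jump"] + 1
        }
      }
    } else if (u < 0.85 && length(theta) > 0L) {
      # within-model rate update
      prop["rate"] <- prop["rate"] + 1
      j <- sample.int(length(theta), 1L)
      if (stats::runif(1L) < 0.5) {
        th_new <- theta
        th_new[j] <- theta[j] * exp(stats::rnorm(1L, 0, sd_rw))
        lr <- log(th_new[j] / theta[j]) +
          log_rate_prior(th_new[j], m_h, v_h) - log_rate_prior(theta[j], m_h, v_h)
        ll_new <- loglik(z, th_new)
        if (is.finite(ll_new) && log(stats::runif(1L)) < ll_new - ll + lr) {
          theta <- th_new; ll <- ll_new; acc["rate"] <- acc["rate"] + 1
        }
      } else {
        th_new <- theta
        th_new[j] <- rgamma_pos(1L, m_h, v_h)
        ll_new <- loglik(z, th_new)
        if (is.finite(ll_new) && log(stats::runif(1L)) < ll_new - ll) {
          theta <- th_new; ll <- ll_new; acc["rate"] <- acc["rate"] + 1
        }
      }
    } else if (prior$update_hyper) {
      prop["hyper"] <- prop["hyper"] + 1
      m_new <- reflect(m_h + stats::rnorm(1L, 0, 0.2), 0, 1)
      v_new <- reflect(v_h + stats::rnorm(1L, 0, 0.2), 0, 1)
      if (m_new > 0 && v_new > 0) {
        dlp <- log_rate_prior(theta, m_new, v_new) - log_rate_prior(theta, m_h, v_h)
        if (log(stats::runif(1L)) < dlp) {
          m_h <- m_new; v_h <- v_new; acc["hyper"] <- acc["hyper"] + 1
        }
      }
    }
    if (it <= burnin && it %% 200L == 0L && prop["rate"] > 0) {
      r_acc <- acc["rate"] / prop["rate"]
      sd_rw <- min(5, max(0.05, sd_rw * exp(r_acc - 0.3)))
    }
    if (it > burnin && (it - burnin) %% thin == 0L && kept < n_keep) {
      kept <- kept + 1L
      samp_it[kept] <- it
      samp_classes[kept] <- length(setdiff(unique(z), 0L))
      samp_zero[kept] <- sum(z == 0L)
      samp_ll[kept] <- ll
      samp_key[kept] <- rj_config_key(z)
      samp_z[[kept]] <- z; samp_theta[[kept]] <- theta
      zero_hits <- zero_hits + (z == 0L)
    }
  }
  idx <- seq_len(kept)
  samples <- data.frame(iteration = samp_it[idx],
                        n_classes = samp_classes[idx],
                        n_zero = samp_zero[idx],
                        logL = samp_ll[idx],
                        config = samp_key[idx],
                        stringsAsFactors = FALSE)
  summary <- list(
    n_classes_mean = mean(samples$n_classes),
    n_classes_range = range(samples$n_classes),
    n_zero_mean = mean(samples$n_zero),
    n_zero_range = range(samples$n_zero),
    zero_proportion = stats::setNames(zero_hits / kept, rate_labels)
  )
  structure(list(samples = samples, summary = summary,
                 z = samp_z[idx], theta = samp_theta[idx],
                 acceptance = ifelse(prop > 0, acc / prop, NA_real_),
                 rate_labels = rate_labels, n_rates = n_rates,
                 seed = seed, thin = thin, burnin = burnin),
            class = "chrom_rj")
}

#' Log Bayes factor from harmonic-mean marginal likelihoods
#'
#' The marginal likelihood of each model is approximated by the harmonic mean
#' of its posterior likelihood samples, computed in log space with
#' log-sum-exp stabilization; the statistic is
#' \eqn{2 (\log HM_1 - \log HM_2)}, with values above 2 conventionally read
#' as positive evidence for model 1.
#'
#' @param samples1,samples2 Data frames with a \code{logL} column (from
#'   \code{mcmc_fixed} or \code{rj_mcmc}), fitted to the same data.
#' @return The statistic, with attribute \code{threshold = 2}.
#' @export
log_bayes_factor <- function(samples1, samples2) {
  h1 <- log_harmonic_mean(extract_logl(samples1))
  h2 <- log_harmonic_mean(extract_logl(samples2))
  structure(2 * (h1 - h2), threshold = 2)
}

extract_logl <- function(x) {
  if (inherits(x, "chrom_mcmc") || inherits(x, "chrom_rj")) x <- x$samples
  if (is.data.frame(x)) x <- x$logL
  if (is.null(x) || length(x) == 0L) stop("no logL samples")
  x
}

log_harmonic_mean <- function(logl) {
  # log[ n / sum(exp(-logl)) ] computed stably
  neg <- -logl
  m <- max(neg)
  log(length(logl)) - (m + log(sum(exp(neg - m))))
}
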