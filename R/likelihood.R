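# Shared pruning machinery: postorder conditional likelihoods with
# per-node log scaling, reused by the likelihood, the marginal
# reconstruction and the stochastic mapping code.
chrom_pruning <- function(tree, counts, model) {
  states <- model$states
  S <- length(states)
  ntip <- ape::Ntip(tree)
  counts <- check_counts(counts, tree)
  bad <- which(!(counts %in% states))
  if (length(bad)) {
    stop("tip count outside the state space: ", names(counts)[bad[1L]],
         " = ", counts[bad[1L]])
  }
  post <- ape::reorder.phylo(tree, "postorder")
  if (is.null(post$edge.length)) stop("tree has no branch lengths")
  kern <- transition_kernel(model$Q)
  nn <- ntip + tree$Nnode
  P <- lapply(post$edge.length, kern)
  down <- matrix(0, nn, S)
  down[(ntip + 1L):nn, ] <- 1
  down[cbind(seq_len(ntip), match(counts[post$tip.label], states))] <- 1
  logsc <- numeric(nn)
  for (k in seq_len(nrow(post$edge))) {
    par <- post$edge[k, 1L]; chi <- post$edge[k, 2L]
    v <- as.vector(P[[k]] %*% down[chi, ])
    down[par, ] <- down[par, ] * v
    logsc[par] <- logsc[par] + logsc[chi]
    m <- max(down[par, ])
    if (!is.finite(m)) {
      stop("non-finite likelihood on branch ", k, " (edge to node ", chi, ")")
    }
    if (m > 0 && m < 1e-280) { down[par, ] <- down[par, ] / m; logsc[par] <- logsc[par] + log(m) }
  }
  root <- ntip + 1L
  list(tree = post, states = states, P = P, down = down, logsc = logsc,
       root = root, ntip = ntip, counts = counts, kern = kern)
}

root_prior_vector <- function(model, root_cond) {
  rp <- model$root_prior
  S <- length(model$states)
  if (is.numeric(rp) && length(rp) == 1L) {
    pi0 <- numeric(S)
    j <- match(as.integer(rp), model$states)
    if (is.na(j)) stop("fixed root state ", rp, " not in the state space")
    pi0[j] <- 1
    return(pi0)
  }
  rp <- match.arg(rp, c("uniform_nonzero", "uniform"))
  if (rp == "uniform") return(rep(1 / S, S))
  nz <- root_cond > 0
  if (!any(nz)) nz <- rep(TRUE, S)
  ifelse(nz, 1 / sum(nz), 0)
}

#' Log-likelihood of chromosome counts on a tree
#'
#' Felsenstein pruning under a chromosome-number CTMC: per-branch transition
#' matrices \eqn{P(t) = \exp(Qt)} are combined from the tips upward, and the
#' root conditional likelihoods are averaged over the configured root prior.
#'
#' @param tree A rooted \code{phylo} with branch lengths.
#' @param counts Named integer vector of haploid counts (one per tip).
#' @param model A \code{chrom_qmodel}.
#' @return The log-likelihood (a single numeric).
#' @export
tree_log_likelihood <- function(tree, counts, model) {
  pr <- chrom_pruning(tree, counts, model)
  rootl <- pr$down[pr$root, ]
  pi0 <- root_prior_vector(model, rootl)
  ll <- sum(pi0 * rootl)
  if (ll <= 0) return(-Inf)
  log(ll) + pr$logsc[pr$root]
}

# parameter transform for the optimizer: rates in log space, linear
# coefficients untransformed
param_transform <- function(pnames) {
  is_rate <- !grepl("_lin$", pnames)
  list(
    to_opt = function(p) ifelse(is_rate, log(pmax(p, 1e-6)), p),
    from_opt = function(x) stats::setNames(ifelse(is_rate, exp(x), x), pnames),
    lower = ifelse(is_rate, log(1e-6), -100),
    upper = ifelse(is_rate, log(1e3), 100),
    is_rate = is_rate
  )
}

#' Fit a chromosome-number model by maximum likelihood
#'
#' Bounded multi-start local optimization (\code{L-BFGS-B}) of the pruning
#' log-likelihood. Rates are optimized in log space within
#' \eqn{[10^{-6}, 10^3]} per unit branch length; the linear coefficients of
#' the \code{LR*} families are unconstrained. The first start is a
#' data-informed guess (parsimony change count divided by tree length), the
#' remaining starts are seeded jitters, so a fit is reproducible given
#' \code{seed}.
#'
#' @param tree Rooted \code{phylo} with branch lengths.
#' @param counts Named integer vector of haploid counts.
#' @param spec A \code{chrom_model_spec}.
#' @param space Optional \code{chrom_space}; defaults to
#'   \code{chrom_state_space(counts)} bounds.
#' @param restarts Number of optimizer starts (default 5).
#' @param seed Integer seed for the start jitter.
#' @param root_prior Passed to \code{build_q}.
#' @return A \code{chrom_fit}: fitted \code{model}, \code{logL}, \code{k},
#'   \code{AIC}, convergence flag and number of restarts used.
#' @export
fit_ml <- function(tree, counts, spec, space = NULL, restarts = 5L, seed = 1L,
                   root_prior = "uniform_nonzero") {
  counts <- check_counts(counts, tree)
  if (is.null(space)) space <- chrom_state_space(counts)
  pnames <- family_param_names(spec$family, space, spec$rate_classes)
  tr <- param_transform(pnames)
  negll <- function(x) {
    p <- tr$from_opt(x)
    m <- suppressWarnings(build_q(spec, p, space, root_prior = root_prior))
    ll <- tryCatch(tree_log_likelihood(tree, counts, m),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  # data-informed initial rate: ordered parsimony changes per unit tree length
  plen <- tryCatch(sankoff_ordered(tree, counts)$length, error = function(e) NA)
  tot <- sum(tree$edge.length)
  rate0 <- if (is.finite(plen) && plen > 0 && tot > 0) plen / tot else 0.5
  start0 <- stats::setNames(ifelse(tr$is_rate, rate0, 0), pnames)
  best <- NULL
  rng <- local({ set.seed(as.integer(seed)); function(n) stats::rnorm(n) })
  for (r in seq_len(max(1L, restarts))) {
    x0 <- tr$to_opt(start0)
    if (r > 1L) x0 <- pmin(pmax(x0 + rng(length(x0)) * 1.5, tr$lower), tr$upper)
    fit <- tryCatch(
      stats::optim(x0, negll, method = "L-BFGS-B",
                   lower = tr$lower, upper = tr$upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  p_hat <- tr$from_opt(best$par)
  model <- suppressWarnings(build_q(spec, p_hat, space, root_prior = root_prior))
  logL <- -best$value
  k <- spec$k
  structure(list(
    model = model, params = p_hat, logL = logL, k = k,
    AIC = 2 * k - 2 * logL,
    converged = best$convergence == 0L,
    restarts = max(1L, restarts),
    data_id = data_fingerprint(tree, counts)
  ), class = "chrom_fit")
}

data_fingerprint <- function(tree, counts) {
  counts <- counts[tree$tip.label]
  paste(ape::write.tree(tree), paste(names(counts), counts, collapse = ";"),
        sep = "#")
}

#' @export
print.chrom_fit <- function(x, ...) {
  cat("chrom_fit: ", x$model$spec$family, "  logL = ", format(x$logL),
      "  k = ", x$k, "  AIC = ", format(x$AIC),
      if (!x$converged) "  (NOT converged)" else "", "\n", sep = "")
  invisible(x)
}

#' Compare fitted models with AIC
#'
#' Computes, for a set of fits on the same data: the difference to the best
#' AIC, Akaike weights \eqn{w_m = \exp(-\Delta_m/2)/\sum \exp(-\Delta/2)},
#' the ratio of the second-best to the best weight, and the number of models
#' excluded once the cumulative Akaike weight of the top-ranked models has
#' reached 0.95 (the models outside the minimal such set).
#'
#' @param fits List of \code{chrom_fit} objects on identical data.
#' @return A \code{data.frame} sorted by AIC with attributes
#'   \code{weight_ratio_2nd_best} and \code{n_excluded_at_0.95}.
#' @export
aic_table <- function(fits) {
  stopifnot(length(fits) >= 2L, all(vapply(fits, inherits, TRUE, "chrom_fit")))
  ids <- vapply(fits, `[[`, "", "data_id")
  if (length(unique(ids)) != 1L) stop("fits come from different data")
  fam <- vapply(fits, function(f) f$model$spec$family, "")
  aic <- vapply(fits, `[[`, 0, "AIC")
  logl <- vapply(fits, `[[`, 0, "logL")
  k <- vapply(fits, function(f) as.numeric(f$k), 0)
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  ord <- order(aic)
  tab <- data.frame(model = fam, k = k, logL = logl, AIC = aic,
                    delta_AIC = delta, akaike_weight = w)[ord, ]
  rownames(tab) <- NULL
  ws <- tab$akaike_weight
  n_in <- which(cumsum(ws) >= 0.95 - 1e-12)[1L]
  attr(tab, "weight_ratio_2nd_best") <- if (length(ws) >= 2L) ws[2L] / ws[1L] else NA_real_
  attr(tab, "n_excluded_at_0.95") <- length(ws) - n_in
  tab
}

#' Fit the whole ChromEvol model family
#'
#' Fits all eight dysploidy/polyploidy families on one tree and returns the
#' list of fits (input to \code{aic_table} and \code{model_average}).
#'
#' @inheritParams fit_ml
#' @param families Character vector of family names (default all eight).
#' @return Named list of \code{chrom_fit}.
#' @export
fit_chromevol_family <- function(tree, counts, space = NULL,
                                 families = CHROMEVOL_FAMILIES,
                                 restarts = 3L, seed = 1L,
                                 root_prior = "uniform_nonzero") {
  counts <- check_counts(counts, tree)
  if (is.null(space)) space <- chrom_state_space(counts)
  fits <- lapply(seq_along(families), function(i) {
    fit_ml(tree, counts, chrom_model_spec(families[i]), space,
           restarts = restarts, seed = seed + i, root_prior = root_prior)
  })
  stats::setNames(fits, families)
}
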