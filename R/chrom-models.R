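#' Define the chromosome-number state space
#'
#' The state space is the integer interval \code{[n_min, n_max]} for the
#' dysploidy/polyploidy models, or the ladder of observed counts for the
#' ordered and full Markov models. When bounds are not given they default to
#' \code{n_min = max(1, min(observed) - 2)} and
#' \code{n_max = 2 * max(observed) + 2}, wide enough that duplications from
#' any observed count stay in range.
#'
#' @param observed Integer vector of observed haploid counts.
#' @param n_min,n_max Optional explicit bounds.
#' @return An object of class \code{chrom_space}.
#' @export
chrom_state_space <- function(observed, n_min = NULL, n_max = NULL) {
  observed <- sort(unique(as.integer(observed)))
  if (length(observed) == 0L) stop("no observed counts")
  if (any(observed < 1L)) stop("haploid counts must be >= 1")
  if (is.null(n_min)) n_min <- max(1L, min(observed) - 2L)
  if (is.null(n_max)) n_max <- 2L * max(observed) + 2L
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  if (n_max <= n_min) stop("n_max must exceed n_min")
  if (any(observed < n_min | observed > n_max)) {
    stop("observed counts fall outside [n_min, n_max]")
  }
  structure(list(n_min = n_min, n_max = n_max, observed = observed),
            class = "chrom_space")
}

CHROMEVOL_FAMILIES <- c("CRND", "CRD", "CRDD", "CRDE",
                        "LRND", "LRD", "LRDD", "LRDE")

# free-parameter names per family, in the order fit_ml optimizes them
family_param_names <- function(family, space = NULL, rate_classes = NULL) {
  switch(family,
    CRND = c("gain", "loss"),
    CRD  = c("gain", "loss", "dupl"),
    CRDD = c("gain", "loss", "dupl"),          # demi constrained equal to dupl
    CRDE = c("gain", "loss", "dupl", "demi"),
    LRND = c("gain", "loss", "gain_lin", "loss_lin"),
    LRD  = c("gain", "loss", "dupl", "gain_lin", "loss_lin"),
    LRDD = c("gain", "loss", "dupl", "gain_lin", "loss_lin"),
    LRDE = c("gain", "loss", "dupl", "demi", "gain_lin", "loss_lin"),
    ORDERED_K = {
      m <- length(space$observed)
      switch(rate_classes,
        one = "rate",
        two = c("rate_up", "rate_down"),
        multi = {
          st <- space$observed
          c(paste0("up_", st[-m], "_", st[-1L]), paste0("down_", st[-1L], "_", st[-m]))
        })
    },
    FULL_MK = {
      st <- space$observed
      pairs <- expand.grid(from = st, to = st)
      pairs <- pairs[pairs$from != pairs$to, ]
      paste0("r_", pairs$from, "_", pairs$to)
    },
    stop("unknown model family: ", family)
  )
}

#' Specify a chromosome-number model
#'
#' Families \code{CRND}, \code{CRD}, \code{CRDD}, \code{CRDE} are
#' constant-rate models with, respectively, no duplication; duplication;
#' duplication with demi-duplication at the same rate; and separately
#' estimated demi-duplication. The \code{LR*} counterparts add linear
#' dependence of the dysploid gain and loss rates on the current count.
#' \code{ORDERED_K} restricts transitions to neighbouring observed counts on
#' the ladder with one, two (up/down) or per-edge (\code{"multi"}) rate
#' classes. \code{FULL_MK} is the general Markov model over the observed
#' counts with all \eqn{n(n-1)} directed rates, optionally grouped into
#' classes (used by the reversible-jump sampler).
#'
#' @param family One of the family names above.
#' @param rate_classes For \code{ORDERED_K}: \code{"one"}, \code{"two"} or
#'   \code{"multi"}. For \code{FULL_MK}: optional integer vector assigning
#'   each directed rate to a class (0 = pinned to zero).
#' @param space A \code{chrom_space}; required for \code{ORDERED_K} and
#'   \code{FULL_MK}.
#' @return An object of class \code{chrom_model_spec} with element \code{k},
#'   the number of free parameters.
#' @export
chrom_model_spec <- function(family, rate_classes = NULL, space = NULL) {
  family <- match.arg(family, c(CHROMEVOL_FAMILIES, "ORDERED_K", "FULL_MK"))
  if (family == "ORDERED_K") {
    if (is.null(space)) stop("ORDERED_K needs the state space (observed ladder)")
    rate_classes <- match.arg(rate_classes, c("one", "two", "multi"))
    k <- switch(rate_classes, one = 1L, two = 2L,
                multi = 2L * (length(space$observed) - 1L))
  } else if (family == "FULL_MK") {
    if (is.null(space)) stop("FULL_MK needs the state space (observed ladder)")
    n_rates <- length(space$observed) * (length(space$observed) - 1L)
    if (is.null(rate_classes)) rate_classes <- seq_len(n_rates)
    if (length(rate_classes) != n_rates) {
      stop("FULL_MK rate-class map must have ", n_rates, " entries")
    }
    k <- length(setdiff(unique(rate_classes), 0L))
  } else {
    k <- length(family_param_names(family))
  }
  structure(list(family = family, rate_classes = rate_classes, k = k),
            class = "chrom_model_spec")
}

#' Build the instantaneous rate matrix of a chromosome-number model
#'
#' For the dysploidy/polyploidy families the states are all integers in
#' \code{[n_min, n_max]} and, from count \eqn{i}: gain \eqn{i \to i+1} at rate
#' \eqn{\lambda (+ \lambda_1 (i - n_{min})} for linear families), loss
#' \eqn{i \to i-1} at rate \eqn{\delta (+ \delta_1 (i - n_{min}))},
#' duplication \eqn{i \to 2i} at rate \eqn{\rho} and demi-duplication at rate
#' \eqn{\mu}: even \eqn{i} goes to \eqn{1.5i}; odd \eqn{i} splits
#' \eqn{\mu/2} to each of \eqn{\lfloor 1.5i \rfloor} and
#' \eqn{\lceil 1.5i \rceil}. Events whose target exceeds \code{n_max} are
#' dropped (the rate is not redirected). Effective rates driven negative by
#' the linear term are clamped to zero with a warning. For \code{ORDERED_K}
#' and \code{FULL_MK} the states are the observed ladder.
#'
#' @param spec A \code{chrom_model_spec}.
#' @param params Named numeric vector of free parameters (see
#'   \code{chrom_model_spec}); for \code{FULL_MK} one rate per class.
#' @param space A \code{chrom_space}.
#' @param root_prior \code{"uniform_nonzero"} (default; uniform over states
#'   with nonzero conditional likelihood at the root), \code{"uniform"}, or a
#'   single integer fixing the root state.
#' @return A \code{chrom_qmodel}: states, rate matrix \code{Q}, a labelled
#'   decomposition of off-diagonal rates by event type, and the spec.
#' @export
build_q <- function(spec, params, space,
                    root_prior = "uniform_nonzero") {
  stopifnot(inherits(spec, "chrom_model_spec"), inherits(space, "chrom_space"))
  fam <- spec$family
  ladder <- fam %in% c("ORDERED_K", "FULL_MK")
  states <- if (ladder) space$observed else space$n_min:space$n_max
  S <- length(states)
  idx <- function(n) match(n, states)
  # components[[type]] is an S x S matrix of labelled rates
  types <- c("gain", "loss", "dupl", "demi")
  comp <- stats::setNames(replicate(4, matrix(0, S, S), simplify = FALSE), types)
  clamped <- 0L

  if (fam %in% CHROMEVOL_FAMILIES) {
    pn <- family_param_names(fam)
    if (!all(pn %in% names(params))) {
      stop("params must contain: ", paste(pn, collapse = ", "))
    }
    p <- params
    lin <- grepl("^LR", fam)
    g1 <- if (lin) p[["gain_lin"]] else 0
    d1 <- if (lin) p[["loss_lin"]] else 0
    rho <- if (fam %in% c("CRD", "CRDD", "CRDE", "LRD", "LRDD", "LRDE")) p[["dupl"]] else 0
    mu <- if (fam %in% c("CRDE", "LRDE")) p[["demi"]]
          else if (fam %in% c("CRDD", "LRDD")) rho else 0
    for (i in states) {
      off <- i - space$n_min
      gi <- p[["gain"]] + g1 * off
      di <- p[["loss"]] + d1 * off
      if (gi < 0) { gi <- 0; clamped <- clamped + 1L }
      if (di < 0) { di <- 0; clamped <- clamped + 1L }
      if (i + 1L <= space$n_max) comp$gain[idx(i), idx(i + 1L)] <- gi
      if (i - 1L >= space$n_min) comp$loss[idx(i), idx(i - 1L)] <- di
      if (rho > 0 && 2L * i <= space$n_max) comp$dupl[idx(i), idx(2L * i)] <- rho
      if (mu > 0) {
        if (i %% 2L == 0L) {
          tgt <- as.integer(1.5 * i)
          if (tgt <= space$n_max && tgt != i) {
            comp$demi[idx(i), idx(tgt)] <- comp$demi[idx(i), idx(tgt)] + mu
          }
        } else {
          for (tgt in c(floor(1.5 * i), ceiling(1.5 * i))) {
            if (tgt <= space$n_max && tgt != i) {
              comp$demi[idx(i), idx(tgt)] <- comp$demi[idx(i), idx(tgt)] + mu / 2
            }
          }
        }
      }
    }
  } else if (fam == "ORDERED_K") {
    pn <- family_param_names(fam, space, spec$rate_classes)
    if (!all(pn %in% names(params))) {
      stop("params must contain: ", paste(pn, collapse = ", "))
    }
    for (j in seq_len(S - 1L)) {
      up <- switch(spec$rate_classes,
                   one = params[["rate"]], two = params[["rate_up"]],
                   multi = params[[paste0("up_", states[j], "_", states[j + 1L])]])
      dn <- switch(spec$rate_classes,
                   one = params[["rate"]], two = params[["rate_down"]],
                   multi = params[[paste0("down_", states[j + 1L], "_", states[j])]])
      comp$gain[j, j + 1L] <- up
      comp$loss[j + 1L, j] <- dn
    }
  } else { # FULL_MK: params holds one rate per class, rate_classes maps rates
    pairs <- full_mk_pairs(space)
    cls <- spec$rate_classes
    for (r in seq_len(nrow(pairs))) {
      cl <- cls[r]
      rate <- if (cl == 0L) 0 else params[[cl]]
      i <- idx(pairs$from[r]); j <- idx(pairs$to[r])
      type <- if (pairs$to[r] > pairs$from[r]) "gain" else "loss"
      comp[[type]][i, j] <- rate
    }
  }

  Q <- comp$gain + comp$loss + comp$dupl + comp$demi
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(states, states)
  if (clamped > 0L) {
    warning(clamped, " effective rate(s) clamped to 0 (linear term)")
  }
  structure(list(states = states, Q = Q, components = comp, spec = spec,
                 params = params, space = space, root_prior = root_prior),
            class = "chrom_qmodel")
}

# directed state pairs of the full Mk model, in a fixed canonical order
full_mk_pairs <- function(space) {
  st <- space$observed
  pairs <- expand.grid(to = st, from = st)[, c("from", "to")]
  pairs <- pairs[pairs$from != pairs$to, ]
  rownames(pairs) <- NULL
  pairs
}

#' @export
print.chrom_qmodel <- function(x, ...) {
  cat("chromosome-number CTMC (", x$spec$family, "), ",
      length(x$states), " states: ", x$states[1L], "..",
      x$states[length(x$states)], "\n", sep = "")
  invisible(x)
}

# --- transition probabilities ------------------------------------------------

# Eigendecomposition-based exp(Qt) with a Pade fallback when Q is close to
# defective. Returns a function of t with per-t caching.
transition_kernel <- function(Q) {
  S <- nrow(Q)
  eig <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eigen <- FALSE
  if (!is.null(eig)) {
    Vi <- tryCatch(solve(eig$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      recon <- eig$vectors %*% (eig$values * Vi)
      err <- max(Mod(recon - Q))
      scale <- max(1, max(abs(Q)))
      if (is.finite(err) && err < 1e-9 * scale) use_eigen <- TRUE
    }
  }
  cache <- new.env(parent = emptyenv())
  function(t) {
    stopifnot(t >= 0)
    key <- format(t, digits = 17)
    if (!is.null(cache[[key]])) return(cache[[key]])
    P <- if (t == 0) {
      diag(S)
    } else if (use_eigen) {
      Re(eig$vectors %*% (exp(eig$values * t) * Vi))
    } else {
      as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
    }
    P[P < 0] <- 0
    P <- P / rowSums(P)
    dimnames(P) <- dimnames(Q)
    cache[[key]] <- P
    P
  }
}

#' Transition probability matrix of a model
#'
#' \eqn{P(t) = \exp(Qt)}, computed by eigendecomposition with a Pade
#' approximation fallback; rows are renormalized to sum to one after clipping
#' numerically negative entries at zero.
#'
#' @param model A \code{chrom_qmodel}.
#' @param t Non-negative branch length.
#' @return The \code{S x S} stochastic matrix.
#' @export
transition_matrix <- function(model, t) {
  transition_kernel(model$Q)(t)
}

#' Size of the reversible-jump rate-class model space
#'
#' The number of ways to partition \code{n_rates} labelled directed rates into
#' rate classes is the Bell number \eqn{B(n)}, computed exactly by the Bell
#' triangle recurrence (for a five-state general Markov model, \eqn{n = 20}
#' rates give about \eqn{5.17 \times 10^{13}} models).
#'
#' @param n_rates Number of directed rates (\eqn{\ge 1}).
#' @return The Bell number as a numeric (exact for \code{n_rates} up to 22,
#'   within double precision).
#' @export
rj_model_space_size <- function(n_rates) {
  stopifnot(n_rates >= 1)
  bell_number(as.integer(n_rates))
}

bell_number <- function(n) {
  # Bell triangle; doubles are exact for the sizes used here (< 2^53)
  row <- 1
  for (i in seq_len(n)) {
    new <- numeric(i + 1L)
    new[1L] <- row[length(row)]
    for (j in seq_len(i)) new[j + 1L] <- new[j] + row[j]
    row <- new
    if (i == n) return(row[1L])
  }
  1
}
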