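# clade identity of every node: sorted tip labels joined by "|"
clade_keys <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  post <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) sets[[i]] <- post$tip.label[i]
  for (k in seq_len(nrow(post$edge))) {
    par <- post$edge[k, 1L]; chi <- post$edge[k, 2L]
    sets[[par]] <- c(sets[[par]], sets[[chi]])
  }
  vapply(sets, function(s) paste(sort(s), collapse = "|"), "")
}

# marginal state probabilities at every node (tips included), by the
# up-down (inside-outside) algorithm on the pruning partials
node_marginals <- function(pr, model) {
  post <- pr$tree
  ntip <- pr$ntip; root <- pr$root
  S <- length(pr$states)
  nn <- ntip + post$Nnode
  pi0 <- root_prior_vector(model, pr$down[root, ])
  # per-edge "message" v_k = P_k %*% down[child_k]
  v <- lapply(seq_len(nrow(post$edge)),
              function(k) as.vector(pr$P[[k]] %*% pr$down[post$edge[k, 2L], ]))
  kids_edges <- split(seq_len(nrow(post$edge)), post$edge[, 1L])
  up <- matrix(0, nn, S)
  up[root, ] <- pi0
  for (k in rev(seq_len(nrow(post$edge)))) {   # preorder
    par <- post$edge[k, 1L]; chi <- post$edge[k, 2L]
    sib <- setdiff(kids_edges[[as.character(par)]], k)
    w <- up[par, ]
    for (k2 in sib) w <- w * v[[k2]]
    u <- as.vector(crossprod(pr$P[[k]], w))
    s <- sum(u)
    up[chi, ] <- if (s > 0) u / s else u
  }
  marg <- up * pr$down
  rs <- rowSums(marg)
  bad <- rs <= 0
  if (any(bad)) stop("zero marginal likelihood at node(s) ",
                     paste(which(bad), collapse = ","))
  marg <- marg / rs
  colnames(marg) <- pr$states
  rownames(marg) <- clade_keys(post)
  marg
}

#' Marginal ancestral reconstruction of chromosome numbers
#'
#' Posterior state probabilities at every internal node conditional on all
#' tip counts, computed by the up-down pruning algorithm under a fitted
#' chromosome-number CTMC; the root uses the model's configured prior.
#'
#' @param tree Rooted \code{phylo} with branch lengths.
#' @param counts Named integer vector of haploid counts.
#' @param model A \code{chrom_qmodel} (typically from \code{fit_ml}).
#' @return A matrix (internal nodes x states) of probabilities; rows are
#'   named by the node's clade (sorted tip labels joined by \code{"|"}),
#'   columns by chromosome number. Attribute \code{states} carries the state
#'   vector and \code{logL} the tree log-likelihood.
#' @export
marginal_reconstruction <- function(tree, counts, model) {
  pr <- chrom_pruning(tree, counts, model)
  marg <- node_marginals(pr, model)
  ntip <- pr$ntip
  out <- marg[(ntip + 1L):nrow(marg), , drop = FALSE]
  attr(out, "states") <- pr$states
  attr(out, "logL") <- log(sum(root_prior_vector(model, pr$down[pr$root, ]) *
                                 pr$down[pr$root, ])) + pr$logsc[pr$root]
  out
}

# classify a single jump from state index i to j given the labelled rate
# components; multi-unit dysploid moves on ladder models count |delta| units
classify_jump <- function(model, i, j, unif_draw) {
  rates <- vapply(model$components, function(m) m[i, j], 0)
  tot <- sum(rates)
  type <- if (tot <= 0) {
    if (model$states[j] > model$states[i]) "gain" else "loss"
  } else {
    names(rates)[findInterval(unif_draw * tot, cumsum(rates),
                              left.open = TRUE) + 1L]
  }
  d <- model$states[j] - model$states[i]
  switch(type,
    gain = c(gain = d, loss = 0, dupl = 0, demi = 0),
    loss = c(gain = 0, loss = -d, dupl = 0, demi = 0),
    dupl = c(gain = 0, loss = 0, dupl = 1, demi = 0),
    demi = c(gain = 0, loss = 0, dupl = 0, demi = 1))
}

#' Expected chromosome events by stochastic mapping
#'
#' Samples full character histories conditional on the tip data: joint node
#' states are drawn from their conditional distribution root-to-tips, then
#' each branch's substitution history is drawn conditional on its endpoints
#' by uniformization (jump counts from the endpoint-conditioned Poisson
#' mixture, the embedded chain bridged through cached powers of the
#' uniformized transition matrix). Each realized jump is classified as a
#' dysploid gain or loss (in chromosome units), a duplication or a
#' demi-duplication by its labelled rate component, and counts are averaged
#' over maps.
#'
#' @param tree Rooted \code{phylo} with branch lengths.
#' @param counts Named integer vector of haploid counts.
#' @param model A \code{chrom_qmodel}.
#' @param n_maps Number of stochastic maps (>= 100).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return A \code{chrom_events} summary (see \code{mp_gl}) with
#'   per-branch expected counts, totals, and \code{gl}; attribute
#'   \code{gl_maps} holds the per-map G-L values.
#' @export
expected_events <- function(tree, counts, model, n_maps = 1000L, seed = 1L) {
  stopifnot(n_maps >= 100L)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(as.integer(seed))

  pr <- chrom_pruning(tree, counts, model)
  post <- pr$tree
  S <- length(pr$states)
  ntip <- pr$ntip; root <- pr$root
  nn <- ntip + post$Nnode
  ne <- nrow(post$edge)

  # joint node states for all maps, sampled top-down
  states_mat <- matrix(0L, n_maps, nn)
  rootw <- root_prior_vector(model, pr$down[root, ]) * pr$down[root, ]
  states_mat[, root] <- sample.int(S, n_maps, replace = TRUE, prob = rootw)
  for (k in rev(seq_len(ne))) {      # preorder
    par <- post$edge[k, 1L]; chi <- post$edge[k, 2L]
    sp <- states_mat[, par]
    for (s in unique(sp)) {
      sel <- which(sp == s)
      w <- pr$P[[k]][s, ] * pr$down[chi, ]
      states_mat[sel, chi] <- sample.int(S, length(sel), replace = TRUE, prob = w)
    }
  }

  # uniformization setup (shared across branches: same Q)
  mu <- max(-diag(model$Q))
  Rpow <- list(diag(S))
  if (mu > 0) Rpow[[2L]] <- diag(S) + model$Q / mu
  get_Rpow <- function(n) {     # R^n, cached
    while (length(Rpow) < n + 1L) {
      Rpow[[length(Rpow) + 1L]] <<- Rpow[[length(Rpow)]] %*% Rpow[[2L]]
    }
    Rpow[[n + 1L]]
  }
  sample_njumps <- function(a, b, t, Pab) {
    lw <- stats::dpois(0:400, mu * t, log = TRUE)
    u <- stats::runif(1L) * Pab
    acc <- 0
    for (n in 0:400) {
      acc <- acc + exp(lw[n + 1L]) * get_Rpow(n)[a, b]
      if (acc >= u) return(n)
    }
    400L
  }

  gains <- numeric(ne); losses <- numeric(ne)
  dupl <- numeric(ne); demi <- numeric(ne)
  gl_maps <- numeric(n_maps)
  gl_branch_maps <- matrix(0, ne, n_maps)
  for (k in seq_len(ne)) {
    if (mu == 0) break
    par <- post$edge[k, 1L]; chi <- post$edge[k, 2L]
    t_k <- post$edge.length[k]
    if (t_k == 0) next
    ab <- paste(states_mat[, par], states_mat[, chi])
    for (key in unique(ab)) {
      sel <- which(ab == key)
      a <- states_mat[sel[1L], par]; b <- states_mat[sel[1L], chi]
      Pab <- pr$P[[k]][a, b]
      for (m in sel) {
        nj <- sample_njumps(a, b, t_k, Pab)
        if (nj == 0L) next
        cur <- a
        for (jstep in seq_len(nj)) {
          w <- Rpow[[2L]][cur, ] * get_Rpow(nj - jstep)[, b]
          nxt <- sample.int(S, 1L, prob = w)
          if (nxt != cur) {
            ev <- classify_jump(model, cur, nxt, stats::runif(1L))
            gains[k] <- gains[k] + ev[["gain"]] / n_maps
            losses[k] <- losses[k] + ev[["loss"]] / n_maps
            dupl[k] <- dupl[k] + ev[["dupl"]] / n_maps
            demi[k] <- demi[k] + ev[["demi"]] / n_maps
            gl_maps[m] <- gl_maps[m] + ev[["gain"]] - ev[["loss"]]
            gl_branch_maps[k, m] <- gl_branch_maps[k, m] + ev[["gain"]] - ev[["loss"]]
            cur <- nxt
          }
        }
      }
    }
  }
  out <- event_summary(post, gains, losses, dupl, demi,
                       method = paste0("map-", model$spec$family))
  attr(out, "gl_maps") <- gl_maps
  attr(out, "gl_branch_maps") <- gl_branch_maps
  attr(out, "n_maps") <- n_maps
  out
}

#' Telescoping gains-minus-losses estimator
#'
#' For models whose only events are unit dysploid changes (no duplication),
#' the expected gains minus losses on a branch equals the difference in
#' expected chromosome number between its child and parent; this cheap
#' estimator cross-checks the stochastic mapping.
#'
#' @inheritParams expected_events
#' @return List with per-branch \code{delta} (E\[child\] - E\[parent\]) and
#'   the tree total \code{gl}.
#' @export
gl_telescoping <- function(tree, counts, model) {
  pr <- chrom_pruning(tree, counts, model)
  marg <- node_marginals(pr, model)
  ev <- as.vector(marg %*% pr$states)
  post <- pr$tree
  delta <- ev[post$edge[, 2L]] - ev[post$edge[, 1L]]
  list(delta = delta, gl = sum(delta), edge = post$edge)
}

#' Akaike-weight model averaging of reconstructions
#'
#' Weighted arithmetic mean of per-model node probability vectors; the
#' standard way to carry model uncertainty into the reconstruction.
#'
#' @param reconstructions List of matrices from
#'   \code{marginal_reconstruction}, on the same tree (identical row and
#'   column names).
#' @param weights Akaike weights, summing to 1.
#' @return A matrix of the same shape; rows still sum to 1.
#' @export
model_average <- function(reconstructions, weights) {
  stopifnot(length(reconstructions) >= 1L,
            length(weights) == length(reconstructions))
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  ref <- reconstructions[[1L]]
  for (r in reconstructions[-1L]) {
    if (!identical(dimnames(r), dimnames(ref))) {
      stop("reconstructions have mismatched node or state sets")
    }
  }
  out <- matrix(0, nrow(ref), ncol(ref), dimnames = dimnames(ref))
  for (i in seq_along(reconstructions)) {
    out <- out + weights[i] * reconstructions[[i]]
  }
  out
}
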