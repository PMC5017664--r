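# Independent brute-force oracles. These deliberately avoid the package's
# pruning/backtrace code paths: likelihoods and marginals are computed by
# exhaustive enumeration over internal-node state assignments, parsimony by
# exhaustive minimization.

# all internal-node state assignments of a rooted tree
enum_internal_assignments <- function(tree, n_states) {
  ntip <- ape::Ntip(tree)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  grid <- expand.grid(rep(list(seq_len(n_states)), length(internal)))
  list(internal = internal, grid = as.matrix(grid))
}

# joint probability of tips by summation over internal states, using
# matrix exponentials per edge (via the package's transition_matrix only
# to get exp(Qt); the summation itself is the oracle)
enum_loglik <- function(tree, counts, model) {
  states <- model$states
  S <- length(states)
  ntip <- ape::Ntip(tree)
  tipst <- match(counts[tree$tip.label], states)
  P <- lapply(tree$edge.length, function(t) expm_ref(model$Q, t))
  en <- enum_internal_assignments(tree, S)
  root <- ntip + 1L
  root_lik <- numeric(S)
  for (g in seq_len(nrow(en$grid))) {
    st <- integer(ntip + tree$Nnode)
    st[seq_len(ntip)] <- tipst
    st[en$internal] <- en$grid[g, ]
    p <- 1
    for (k in seq_len(nrow(tree$edge))) {
      p <- p * P[[k]][st[tree$edge[k, 1L]], st[tree$edge[k, 2L]]]
    }
    root_lik[st[root]] <- root_lik[st[root]] + p
  }
  pi0 <- oracle_root_prior(model, root_lik)
  log(sum(pi0 * root_lik))
}

# reference matrix exponential independent of the package's kernel
expm_ref <- function(Q, t) {
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
  dimnames(P) <- dimnames(Q)
  P
}

oracle_root_prior <- function(model, root_lik) {
  rp <- model$root_prior
  S <- length(model$states)
  if (is.numeric(rp)) {
    pi0 <- numeric(S); pi0[match(rp, model$states)] <- 1
    return(pi0)
  }
  if (identical(rp, "uniform")) return(rep(1 / S, S))
  nz <- root_lik > 0
  ifelse(nz, 1 / sum(nz), 0)
}

# marginal node probabilities by Bayes-rule enumeration
enum_marginals <- function(tree, counts, model) {
  states <- model$states
  S <- length(states)
  ntip <- ape::Ntip(tree)
  tipst <- match(counts[tree$tip.label], states)
  P <- lapply(tree$edge.length, function(t) expm_ref(model$Q, t))
  en <- enum_internal_assignments(tree, S)
  root <- ntip + 1L
  # two passes: root conditionals first (to resolve the root prior), then
  # weighted joint probabilities
  root_lik <- numeric(S)
  joint <- matrix(0, length(en$internal), S)
  weights <- numeric(nrow(en$grid))
  for (g in seq_len(nrow(en$grid))) {
    st <- integer(ntip + tree$Nnode)
    st[seq_len(ntip)] <- tipst
    st[en$internal] <- en$grid[g, ]
    p <- 1
    for (k in seq_len(nrow(tree$edge))) {
      p <- p * P[[k]][st[tree$edge[k, 1L]], st[tree$edge[k, 2L]]]
    }
    root_lik[st[root]] <- root_lik[st[root]] + p
    weights[g] <- p
  }
  pi0 <- oracle_root_prior(model, root_lik)
  for (g in seq_len(nrow(en$grid))) {
    w <- weights[g] * pi0[en$grid[g, match(root, en$internal)]]
    for (j in seq_along(en$internal)) {
      joint[j, en$grid[g, j]] <- joint[j, en$grid[g, j]] + w
    }
  }
  marg <- joint / rowSums(joint)
  rownames(marg) <- clade_keys_oracle(tree)[en$internal]
  colnames(marg) <- states
  marg
}

clade_keys_oracle <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  vapply(seq_len(nn), function(v) {
    tips <- if (v <= ntip) tree$tip.label[v] else {
      tree$tip.label[ape::prop.part(tree)[[v - ntip]]]
    }
    paste(sort(tips), collapse = "|")
  }, "")
}

# exhaustive ordered parsimony: minimum total |parent - child| over all
# internal assignments, and the per-node sets of states in optimal ones
brute_sankoff <- function(tree, counts) {
  states <- seq.int(min(counts), max(counts))
  S <- length(states)
  ntip <- ape::Ntip(tree)
  tipst <- counts[tree$tip.label]
  en <- enum_internal_assignments(tree, S)
  costs <- numeric(nrow(en$grid))
  for (g in seq_len(nrow(en$grid))) {
    st <- numeric(ntip + tree$Nnode)
    st[seq_len(ntip)] <- tipst
    st[en$internal] <- states[en$grid[g, ]]
    costs[g] <- sum(abs(st[tree$edge[, 1L]] - st[tree$edge[, 2L]]))
  }
  best <- min(costs)
  opt <- en$grid[abs(costs - best) < 1e-9, , drop = FALSE]
  mpr <- lapply(seq_along(en$internal), function(j) sort(unique(states[opt[, j]])))
  names(mpr) <- en$internal
  list(length = best, mpr = mpr, internal = en$internal)
}

# exhaustive window-count mode: maximum number of observations coverable by
# a closed window of half-width h (count oracle; the estimator must attain it)
max_window_count <- function(values, h) {
  cand <- sort(unique(c(values, values + h, values - h,
                        (rep(values, each = length(values)) +
                           rep(values, length(values))) / 2)))
  max(vapply(cand, function(t) sum(values >= t - h & values <= t + h), 0L))
}

# root-to-tip path lengths
node_depth_to_tips <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  d[seq_len(ape::Ntip(tree))]
}

# random rooted binary tree with branch lengths, deterministic by seed
random_tree <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tips, rooted = TRUE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  tr
}

random_counts <- function(tree, states, seed) {
  set.seed(seed)
  stats::setNames(sample(states, ape::Ntip(tree), replace = TRUE),
                  tree$tip.label)
}

# small ladder-model helper used in several files
ladder_model <- function(states, rate_up, rate_down, root_prior = "uniform") {
  sp <- chrom_state_space(states, min(states), max(states))
  sp$observed <- as.integer(states)
  spec <- chrom_model_spec("ORDERED_K", "two", sp)
  build_q(spec, c(rate_up = rate_up, rate_down = rate_down), sp,
          root_prior = root_prior)
}
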