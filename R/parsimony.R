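#' Ordered Sankoff parsimony reconstruction
#'
#' Chromosome number treated as an ordered multistate character: the cost of
#' changing from count \eqn{i} to \eqn{j} is \eqn{|i - j|} chromosome steps.
#' States range over all integers between the smallest and largest observed
#' count, so unobserved intermediates are valid internal states. Per-node
#' cost vectors are filled tip-to-root; the most-parsimonious reconstruction
#' (MPR) state sets are recovered by a root-to-tip backtrace, and ties are
#' retained.
#'
#' @param tree Rooted \code{phylo} (branch lengths ignored).
#' @param counts Named integer vector of haploid counts for every tip.
#' @return A \code{chrom_mpr}: \code{length} (the parsimony length in
#'   chromosome steps), \code{states} (the ordered state vector),
#'   \code{mpr} (list of attainable state sets per node, indexed by ape node
#'   id) and \code{cost} (the per-node Sankoff cost matrix).
#' @export
sankoff_ordered <- function(tree, counts) {
  counts <- check_counts(counts, tree)
  states <- seq.int(min(counts), max(counts))
  S <- length(states)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  post <- ape::reorder.phylo(tree, "postorder")
  INF <- .Machine$double.xmax / 4
  cost <- matrix(0, nn, S)
  cost[seq_len(ntip), ] <- INF
  cost[cbind(seq_len(ntip), match(counts[post$tip.label], states))] <- 0
  step <- abs(outer(states, states, "-"))   # step[i, j] = |state_i - state_j|
  # min over child state t of (|s - t| + cost[chi, t]), for all s at once
  for (k in seq_len(nrow(post$edge))) {
    par <- post$edge[k, 1L]; chi <- post$edge[k, 2L]
    thr <- apply(step + rep(cost[chi, ], each = S), 1L, min)
    cost[par, ] <- cost[par, ] + thr
  }
  root <- ntip + 1L
  plen <- min(cost[root, ])
  # backtrace: state sets attainable in at least one MPR
  mpr <- vector("list", nn)
  mpr[[root]] <- states[abs(cost[root, ] - plen) < 1e-9]
  pre <- rev(seq_len(nrow(post$edge)))
  for (k in pre) {
    par <- post$edge[k, 1L]; chi <- post$edge[k, 2L]
    ok <- logical(S)
    for (s in match(mpr[[par]], states)) {
      through <- step[s, ] + cost[chi, ]
      ok <- ok | (abs(through - min(through)) < 1e-9)
    }
    mpr[[chi]] <- states[ok]
  }
  structure(list(length = plen, states = states, mpr = mpr, cost = cost,
                 tree = post, counts = counts),
            class = "chrom_mpr")
}

#' @export
print.chrom_mpr <- function(x, ...) {
  cat("ordered parsimony reconstruction: length ", x$length,
      " steps, root MPR {", paste(x$mpr[[ape::Ntip(x$tree) + 1L]], collapse = ","),
      "}\n", sep = "")
  invisible(x)
}

# all joint most-parsimonious assignments (internal nodes), for small trees
joint_mprs <- function(recon, max_tips = 20L, max_combos = 2e5) {
  tree <- recon$tree
  ntip <- ape::Ntip(tree)
  if (ntip > max_tips) stop("joint MPR enumeration limited to ", max_tips, " tips")
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  cand <- recon$mpr[internal]
  n_comb <- prod(lengths(cand))
  if (n_comb > max_combos) stop("too many MPR candidate combinations: ", n_comb)
  grid <- as.matrix(expand.grid(cand, KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- as.character(internal)
  full_states <- function(assign) {
    st <- numeric(ntip + tree$Nnode)
    st[seq_len(ntip)] <- recon$counts[tree$tip.label]
    st[internal] <- assign
    st
  }
  costs <- apply(grid, 1L, function(assign) {
    st <- full_states(assign)
    sum(abs(st[tree$edge[, 1L]] - st[tree$edge[, 2L]]))
  })
  grid[abs(costs - recon$length) < 1e-9, , drop = FALSE]
}

#' Parsimony gains-minus-losses statistic
#'
#' Traverses the tree from root to tips summing the signed difference between
#' parent and child states in chromosome units (a two-step change counts as
#' two). With reconstruction ambiguity, branch changes are averaged over the
#' possible parent/child state pairs: \code{mode = "marginal"} (default)
#' averages uniformly over the product of the two nodes' MPR sets per branch;
#' \code{mode = "joint"} averages over all joint most-parsimonious
#' assignments (exact, enumerated; trees up to 20 tips).
#'
#' @param tree Rooted \code{phylo} (must match the reconstruction).
#' @param recon A \code{chrom_mpr} from \code{sankoff_ordered}.
#' @param counts The count table used for the reconstruction.
#' @param mode \code{"marginal"} or \code{"joint"}.
#' @return A \code{data.frame}-free summary list of class
#'   \code{chrom_events}: per-branch expected \code{gains} and \code{losses}
#'   and totals, with \code{gl = gains_total - losses_total} (possibly
#'   fractional).
#' @export
mp_gl <- function(tree, recon, counts, mode = c("marginal", "joint")) {
  mode <- match.arg(mode)
  stopifnot(inherits(recon, "chrom_mpr"))
  post <- recon$tree
  ntip <- ape::Ntip(post)
  counts <- check_counts(counts, post)
  if (!identical(unname(counts), unname(recon$counts[names(counts)]))) {
    stop("counts differ from those used for the reconstruction")
  }
  ne <- nrow(post$edge)
  gains <- numeric(ne); losses <- numeric(ne)
  if (mode == "marginal") {
    node_set <- function(v) {
      if (v <= ntip) counts[post$tip.label[v]] else recon$mpr[[v]]
    }
    for (k in seq_len(ne)) {
      ps <- node_set(post$edge[k, 1L]); cs <- node_set(post$edge[k, 2L])
      d <- outer(cs, ps, "-")           # child minus parent
      gains[k] <- mean(pmax(d, 0))
      losses[k] <- mean(pmax(-d, 0))
    }
  } else {
    assigns <- joint_mprs(recon)
    st <- matrix(0, nrow(assigns), ntip + post$Nnode)
    st[, seq_len(ntip)] <- matrix(counts[post$tip.label], nrow(assigns), ntip,
                                  byrow = TRUE)
    st[, (ntip + 1L):(ntip + post$Nnode)] <- assigns
    for (k in seq_len(ne)) {
      d <- st[, post$edge[k, 2L]] - st[, post$edge[k, 1L]]
      gains[k] <- mean(pmax(d, 0))
      losses[k] <- mean(pmax(-d, 0))
    }
  }
  event_summary(post, gains, losses,
                dupl = numeric(ne), demi = numeric(ne),
                method = paste0("MP-", mode))
}

event_summary <- function(tree, gains, losses, dupl, demi, method) {
  structure(list(
    tree = tree, method = method,
    branch = data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L],
                        gains = gains, losses = losses,
                        duplications = dupl, demi_duplications = demi),
    gains_total = sum(gains), losses_total = sum(losses),
    duplications_total = sum(dupl), demi_duplications_total = sum(demi),
    gl = sum(gains) - sum(losses)
  ), class = "chrom_events")
}

#' @export
print.chrom_events <- function(x, ...) {
  cat("event summary (", x$method, "): gains ", format(x$gains_total),
      ", losses ", format(x$losses_total),
      ", duplications ", format(x$duplications_total),
      ", demi-duplications ", format(x$demi_duplications_total),
      ", G-L = ", format(x$gl), "\n", sep = "")
  invisible(x)
}
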