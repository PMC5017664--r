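#' Read a set of rooted trees
#'
#' Reads one or more rooted trees with branch lengths from a Newick or NEXUS
#' file into a tree set (an ape \code{multiPhylo} with a shared taxon
#' namespace). NEXUS translate tables are honoured, so numeric tip tokens are
#' restored to taxon labels.
#'
#' @param path Path to the tree file.
#' @param format Either \code{"newick"} or \code{"nexus"}; defaults to a guess
#'   from the file extension (\code{.nex}/\code{.nexus} means NEXUS).
#' @param provenance Optional character tag recorded on the returned set.
#' @return A \code{multiPhylo} object with attributes \code{taxa} (the shared
#'   tip-label set) and \code{provenance}.
#' @export
read_tree_set <- function(path, format = NULL, provenance = basename(path)) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.nex(us)?$", path, ignore.case = TRUE)) "nexus" else "newick"
  }
  format <- match.arg(format, c("newick", "nexus"))
  trees <- tryCatch(
    if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path),
    error = function(e) stop("failed to parse ", format, " file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (inherits(trees, "phylo")) trees <- c(structure(list(trees), class = "multiPhylo"))
  if (length(trees) == 0L) stop("no trees found in ", path)
  as_tree_set(trees, provenance = provenance)
}

#' Assemble a tree set from a list of trees
#'
#' Validates that all trees share one taxon namespace and are rooted.
#'
#' @param trees A \code{multiPhylo} or list of \code{phylo} objects.
#' @param provenance Optional character tag.
#' @return A validated \code{multiPhylo} with \code{taxa} and
#'   \code{provenance} attributes.
#' @export
as_tree_set <- function(trees, provenance = NA_character_) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(trees, function(tr) {
    stopifnot(inherits(tr, "phylo"))
    tr
  })
  taxa <- sort(trees[[1L]]$tip.label)
  if (anyDuplicated(taxa)) stop("duplicate tip labels in tree 1")
  for (i in seq_along(trees)) {
    ti <- sort(trees[[i]]$tip.label)
    if (!identical(ti, taxa)) {
      stop("tree ", i, " has a different taxon set than tree 1")
    }
  }
  class(trees) <- "multiPhylo"
  attr(trees, "taxa") <- taxa
  attr(trees, "provenance") <- provenance
  trees
}

#' Rescale a tree to a fixed total branch length
#'
#' Multiplies every branch length by one constant so the sum of all branch
#' lengths equals \code{target}. Rescaling all trees of a sample to a common
#' total length (default 5, one unit per character state in the motivating
#' five-state data) makes rate estimates comparable across phylograms and
#' chronograms.
#'
#' @param tree A \code{phylo} object with branch lengths.
#' @param target Positive total length; default 5.
#' @return The rescaled tree.
#' @export
rescale_total_length <- function(tree, target = 5) {
  stopifnot(inherits(tree, "phylo"), is.numeric(target), target > 0)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  tot <- sum(tree$edge.length)
  if (tot <= 0) stop("tree total length must be > 0 to rescale")
  tree$edge.length <- tree$edge.length * (target / tot)
  tree
}

#' Prune taxa from a rooted tree
#'
#' Removes the given tips; internal nodes left with a single child are
#' suppressed and their branch lengths summed, so patristic distances among
#' the retained tips are preserved exactly.
#'
#' @param tree A \code{phylo} object.
#' @param drop Character vector of tip labels to remove (may be empty).
#' @return The pruned tree.
#' @export
prune_taxa <- function(tree, drop) {
  stopifnot(inherits(tree, "phylo"))
  if (length(drop) == 0L) return(tree)
  unknown <- setdiff(drop, tree$tip.label)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (length(tree$tip.label) - length(drop) < 2L) {
    stop("fewer than 2 tips would remain after pruning")
  }
  ape::drop.tip(tree, drop, collapse.singles = TRUE)
}

node_depths <- function(tree) {
  # root-to-node path lengths, indexed by node id
  tree <- ape::reorder.phylo(tree, "postorder")
  n_node <- ape::Ntip(tree) + tree$Nnode
  depth <- numeric(n_node)
  root <- ape::Ntip(tree) + 1L
  # preorder: parents before children
  ord <- rev(seq_len(nrow(tree$edge)))
  for (k in ord) {
    par <- tree$edge[k, 1L]; chi <- tree$edge[k, 2L]
    depth[chi] <- depth[par] + tree$edge.length[k]
  }
  depth
}

#' Make a tree ultrametric by mean path-length smoothing
#'
#' Returns a tree with identical topology in which every root-to-tip path has
#' the same length. Each internal node's depth is set recursively so that the
#' tips of its subtree become equidistant from it, using the mean path length
#' over the subtree's tips; the root-to-tip depth equals the mean original
#' root-to-tip distance.
#'
#' @param tree A rooted \code{phylo} with branch lengths.
#' @return An ultrametric tree with the same topology and tip set.
#' @export
ultrametricize <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  post <- ape::reorder.phylo(tree, "postorder")
  nn <- ntip + tree$Nnode
  # mean distance from each node down to its subtree's tips; postorder
  # guarantees a child's mean is final before its parent accumulates it
  sumdown <- numeric(nn)
  wt <- integer(nn); wt[seq_len(ntip)] <- 1L
  mdown <- numeric(nn)
  for (k in seq_len(nrow(post$edge))) {
    par <- post$edge[k, 1L]; chi <- post$edge[k, 2L]
    if (chi > ntip) mdown[chi] <- sumdown[chi] / wt[chi]
    sumdown[par] <- sumdown[par] + (mdown[chi] + post$edge.length[k]) * wt[chi]
    wt[par] <- wt[par] + wt[chi]
  }
  mdown[root] <- sumdown[root] / wt[root]
  # preorder: fix each node's height above the tips, never exceeding parent
  height <- numeric(nn)           # smoothed distance to tips
  height[root] <- mdown[root]
  for (k in rev(seq_len(nrow(post$edge)))) {
    par <- post$edge[k, 1L]; chi <- post$edge[k, 2L]
    height[chi] <- if (chi <= ntip) 0 else min(mdown[chi], height[par])
  }
  new_len <- height[post$edge[, 1L]] - height[post$edge[, 2L]]
  out <- post
  out$edge.length <- pmax(new_len, 0)
  ape::reorder.phylo(out, "cladewise")
}

#' Colless imbalance index
#'
#' Sum over internal nodes of the absolute difference in tip counts between
#' the two daughter clades. The normalized form divides by
#' \eqn{(T-1)(T-2)/2}, its maximum on a caterpillar tree with \eqn{T} tips.
#'
#' @param tree A fully resolved (binary) rooted \code{phylo}.
#' @param normalized Return the normalized index in \[0, 1\]?
#' @return A single numeric value.
#' @export
colless_index <- function(tree, normalized = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  if (tree$Nnode != ntip - 1L) {
    stop("tree contains polytomies; resolve (e.g. multi2di) or skip it")
  }
  post <- ape::reorder.phylo(tree, "postorder")
  nn <- ntip + tree$Nnode
  sz <- integer(nn); sz[seq_len(ntip)] <- 1L
  kids <- vector("list", nn)
  for (k in seq_len(nrow(post$edge))) {
    par <- post$edge[k, 1L]; chi <- post$edge[k, 2L]
    sz[par] <- sz[par] + sz[chi]
    kids[[par]] <- c(kids[[par]], chi)
  }
  raw <- 0L
  for (v in (ntip + 1L):nn) raw <- raw + abs(sz[kids[[v]][1L]] - sz[kids[[v]][2L]])
  if (!normalized) return(as.numeric(raw))
  if (ntip < 3L) return(0)
  raw * 2 / ((ntip - 1) * (ntip - 2))
}

#' Non-cumulative stemminess
#'
#' For every non-root internal node \eqn{v} with stem (parent) branch length
#' \eqn{s_v}: the \code{bounded} variant scores
#' \eqn{s_v / (s_v + L_v)} where \eqn{L_v} is the total branch length of
#' \eqn{v}'s subtree (values in \[0, 1\]); the \code{ratio} variant scores
#' \eqn{s_v} divided by the summed lengths of \eqn{v}'s immediate child
#' branches (unbounded above). Returns the mean over nodes; nodes with a zero
#' denominator are skipped (counted in the \code{skipped} attribute).
#'
#' @param tree A rooted \code{phylo} with branch lengths.
#' @param variant \code{"ratio"} (default) or \code{"bounded"}.
#' @return Mean stemminess with attributes \code{variant} and \code{skipped}.
#' @export
stemminess <- function(tree, variant = c("ratio", "bounded")) {
  variant <- match.arg(variant)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  post <- ape::reorder.phylo(tree, "postorder")
  nn <- ntip + tree$Nnode
  subtot <- numeric(nn)    # total branch length below node
  childsum <- numeric(nn)  # immediate child branch lengths
  stem <- rep(NA_real_, nn)
  for (k in seq_len(nrow(post$edge))) {
    par <- post$edge[k, 1L]; chi <- post$edge[k, 2L]
    subtot[par] <- subtot[par] + subtot[chi] + post$edge.length[k]
    childsum[par] <- childsum[par] + post$edge.length[k]
    stem[chi] <- post$edge.length[k]
  }
  internal <- setdiff((ntip + 1L):nn, root)
  vals <- numeric(0); skipped <- 0L
  for (v in internal) {
    den <- if (variant == "bounded") stem[v] + subtot[v] else childsum[v]
    if (!is.finite(den) || den <= 0) { skipped <- skipped + 1L; next }
    vals <- c(vals, stem[v] / den)
  }
  if (skipped > 0L) warning(skipped, " node(s) skipped (zero denominator)")
  structure(mean(vals), variant = variant, skipped = skipped)
}

#' Tree-shape diagnostics
#'
#' Convenience wrapper returning the Colless index (raw and normalized),
#' stemminess (both variants) and the total branch length of a tree.
#'
#' @param tree A binary rooted \code{phylo} with branch lengths.
#' @return A one-row \code{data.frame}.
#' @export
shape_stats <- function(tree) {
  data.frame(
    colless_raw = colless_index(tree, normalized = FALSE),
    colless_normalized = colless_index(tree, normalized = TRUE),
    stemminess_ratio = as.numeric(stemminess(tree, "ratio")),
    stemminess_bounded = as.numeric(stemminess(tree, "bounded")),
    total_length = sum(tree$edge.length)
  )
}
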