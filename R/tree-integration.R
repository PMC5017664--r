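# internal clade keys (non-trivial rooted clades: >1 tip, not needed for root?
# the root clade spanning all taxa is included; tips are excluded)
tree_clades <- function(tree) {
  ntip <- ape::Ntip(tree)
  keys <- clade_keys(tree)
  keys[(ntip + 1L):length(keys)]
}

#' Rooted clade frequencies across a tree set
#'
#' Counts every internal-node clade (identified by its taxon set; trees are
#' rooted throughout) and normalizes by the number of trees.
#'
#' @param trees A \code{multiPhylo} tree set sharing one taxon namespace.
#' @return A \code{data.frame} with \code{clade} (sorted tip labels joined by
#'   \code{"|"}), \code{count}, \code{frequency} and \code{size}, ordered by
#'   decreasing frequency then decreasing size.
#' @export
clade_frequencies <- function(trees) {
  trees <- as_tree_set(trees)
  tab <- table(unlist(lapply(trees, tree_clades)))
  df <- data.frame(clade = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df$frequency <- df$count / length(trees)
  df$size <- lengths(strsplit(df$clade, "|", fixed = TRUE))
  df[order(-df$frequency, -df$size, df$clade), , drop = FALSE]
}

#' Majority-rule consensus of a rooted tree set
#'
#' Returns the tree containing exactly the clades whose frequency is at least
#' \code{threshold}; with a threshold of at least 0.5 those clades are
#' mutually compatible, and regions without qualifying clades collapse to
#' polytomies.
#'
#' @param trees A \code{multiPhylo} tree set.
#' @param threshold Clade-frequency threshold in \[0.5, 1\]; default 0.95.
#' @return A rooted \code{phylo} (no branch lengths) with
#'   \code{node.label} set to the clade frequencies.
#' @export
majority_consensus <- function(trees, threshold = 0.95) {
  stopifnot(threshold >= 0.5)
  trees <- as_tree_set(trees)
  taxa <- attr(trees, "taxa")
  cf <- clade_frequencies(trees)
  keep <- cf[cf$frequency >= threshold - 1e-12, , drop = FALSE]
  build_clade_tree(taxa, strsplit(keep$clade, "|", fixed = TRUE),
                   labels = format(keep$frequency, digits = 4))
}

# build a rooted tree from a set of nested taxon subsets (must include or
# will be given the root clade); subsets assumed pairwise compatible
build_clade_tree <- function(taxa, clade_sets, labels = NULL) {
  clade_sets <- lapply(clade_sets, sort)
  keys <- vapply(clade_sets, paste, "", collapse = "|")
  rootkey <- paste(sort(taxa), collapse = "|")
  if (!(rootkey %in% keys)) {
    clade_sets <- c(clade_sets, list(sort(taxa)))
    keys <- c(keys, rootkey)
    labels <- if (!is.null(labels)) c(labels, "")
  }
  dup <- duplicated(keys)
  clade_sets <- clade_sets[!dup]; keys <- keys[!dup]
  if (!is.null(labels)) labels <- labels[!dup]
  sizes <- lengths(clade_sets)
  ord <- order(sizes)           # smallest first; parents found among larger
  n_cl <- length(clade_sets)
  parent_of <- integer(n_cl)    # index into clade_sets
  for (a in seq_len(n_cl)) {
    best <- 0L; best_size <- Inf
    for (b in seq_len(n_cl)) {
      if (b == a || sizes[b] <= sizes[a]) next
      if (all(clade_sets[[a]] %in% clade_sets[[b]]) && sizes[b] < best_size) {
        best <- b; best_size <- sizes[b]
      }
    }
    parent_of[a] <- best        # 0 for the root clade
  }
  # assign each taxon to its smallest containing clade
  ntip <- length(taxa)
  tip_parent <- vapply(taxa, function(tx) {
    containing <- which(vapply(clade_sets, function(s) tx %in% s, TRUE))
    containing[which.min(sizes[containing])]
  }, 0L)
  # ape numbering: tips 1..ntip, internal nodes ntip+1.., root first
  root_idx <- which(parent_of == 0L)
  internal_order <- c(root_idx, setdiff(order(-sizes), root_idx))
  node_id <- integer(n_cl)
  node_id[internal_order] <- ntip + seq_len(n_cl)
  edge <- rbind(
    cbind(node_id[parent_of[parent_of != 0L]], node_id[which(parent_of != 0L)]),
    cbind(node_id[tip_parent], seq_len(ntip))
  )
  tr <- list(edge = edge, tip.label = taxa, Nnode = n_cl,
             node.label = if (!is.null(labels)) labels[internal_order])
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Maximum clade credibility tree
#'
#' Scores every member of the set by the sum of the log clade frequencies of
#' its internal nodes (the product-of-credibilities convention;
#' \code{score = "sum"} uses the plain sum of frequencies instead) and
#' returns the best member; ties are broken by the lowest tree index.
#'
#' @param trees A \code{multiPhylo} tree set.
#' @param score \code{"log"} (default) or \code{"sum"}.
#' @return The winning \code{phylo}, with attributes \code{index} and
#'   \code{score}.
#' @export
mcc_tree <- function(trees, score = c("log", "sum")) {
  score <- match.arg(score)
  trees <- as_tree_set(trees)
  cf <- clade_frequencies(trees)
  freq <- stats::setNames(cf$frequency, cf$clade)
  scores <- vapply(trees, function(tr) {
    f <- freq[tree_clades(tr)]
    if (score == "log") sum(log(f)) else sum(f)
  }, 0)
  best <- which.max(scores)   # which.max returns the first (lowest index) tie
  structure(trees[[best]], index = best, score = scores[best],
            score_convention = score)
}

#' Integrate per-tree reconstructions onto a target tree's clades
#'
#' For every internal-node clade of the target (consensus or MCC) tree,
#' averages the node probability vectors from all trees that contain that
#' clade.
#'
#' @param trees A \code{multiPhylo} tree set.
#' @param recons List (parallel to \code{trees}) of matrices from
#'   \code{marginal_reconstruction} (rows named by clade key), or of
#'   per-clade probability matrices generally.
#' @param target A rooted \code{phylo} whose clades to integrate onto.
#' @return A list: \code{probs} (matrix, target clades x states),
#'   \code{n_contributing} (trees containing each clade), \code{clades}.
#' @export
integrate_reconstructions <- function(trees, recons, target) {
  trees <- as_tree_set(trees)
  stopifnot(length(recons) == length(trees))
  states <- colnames(recons[[1L]])
  tclades <- tree_clades(target)
  probs <- matrix(0, length(tclades), length(states),
                  dimnames = list(tclades, states))
  n_contrib <- integer(length(tclades))
  for (i in seq_along(recons)) {
    r <- recons[[i]]
    hit <- intersect(tclades, rownames(r))
    probs[hit, ] <- probs[hit, , drop = FALSE] + r[hit, , drop = FALSE]
    n_contrib[match(hit, tclades)] <- n_contrib[match(hit, tclades)] + 1L
  }
  if (any(n_contrib == 0L)) {
    stop("clade(s) absent from every tree: ",
         paste(tclades[n_contrib == 0L], collapse = "; "))
  }
  probs <- probs / n_contrib
  list(probs = probs, n_contributing = stats::setNames(n_contrib, tclades),
       clades = tclades)
}
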