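#' Write trees as NEXUS with node annotations
#'
#' Writes a TREES block with a translate table; per-node annotations (for
#' example clade frequencies or reconstruction probabilities) are emitted as
#' BEAST-style bracketed comments on internal nodes, keyed by the node's
#' clade so downstream tools can draw probability pies.
#'
#' @param trees A \code{phylo} or \code{multiPhylo}.
#' @param path Output path.
#' @param annotations Either \code{NULL}, a named list keyed by clade key
#'   (sorted tip labels joined by \code{"|"}) whose elements are named
#'   vectors of annotation values, or a list of such lists (one per tree).
#' @return \code{path}, invisibly.
#' @export
write_annotated_nexus <- function(trees, path, annotations = NULL) {
  if (inherits(trees, "phylo")) {
    trees <- list(trees)
    if (!is.null(annotations) && !is.null(names(annotations))) {
      annotations <- list(annotations)
    }
  }
  taxa <- trees[[1L]]$tip.label
  lines <- c("#NEXUS", "", "BEGIN TREES;", "\tTRANSLATE")
  trans <- paste0("\t\t", seq_along(taxa), " ", taxa,
                  c(rep(",", length(taxa) - 1L), ";"))
  lines <- c(lines, trans)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    tr2 <- tr
    tr2$tip.label <- as.character(match(tr$tip.label, taxa))
    ann <- if (is.null(annotations)) NULL else annotations[[i]]
    # annotation keys refer to taxon names; remap the tree only for labels
    nk <- newick_with_annotations_translated(tr, taxa, ann)
    lines <- c(lines, paste0("\tTREE tree_", i, " = ", nk))
  }
  lines <- c(lines, "END;")
  writeLines(lines, path)
  invisible(path)
}

newick_with_annotations_translated <- function(tree, taxa, annotations) {
  ntip <- ape::Ntip(tree)
  keys <- clade_keys(tree)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  has_bl <- !is.null(tree$edge.length)
  stem <- if (has_bl) stats::setNames(tree$edge.length, tree$edge[, 2L]) else numeric(0)
  ann_str <- function(v) {
    if (is.null(annotations)) return("")
    a <- annotations[[keys[v]]]
    if (is.null(a)) return("")
    if (!is.null(names(a))) {
      paste0("[&", paste0(names(a), "=", a, collapse = ","), "]")
    } else paste0("[&", paste(a, collapse = ","), "]")
  }
  rec <- function(v) {
    bl <- if (has_bl && !is.na(stem[as.character(v)])) {
      paste0(":", format(stem[as.character(v)], digits = 12))
    } else ""
    if (v <= ntip) {
      return(paste0(match(tree$tip.label[v], taxa), bl))
    }
    inner <- paste(vapply(kids[[as.character(v)]], rec, ""), collapse = ",")
    paste0("(", inner, ")", ann_str(v), bl)
  }
  paste0(rec(ntip + 1L), ";")
}
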