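#' Node-wise reconstruction precision
#'
#' Normalized precision of a node's reconstruction over the state union
#' \eqn{X}: \eqn{RP_n = (C_X \max_j P_j - 1) / (C_X - 1)}, where \eqn{C_X}
#' is the number of states in \eqn{X}. Equals 1 for a point reconstruction
#' and 0 for the uniform distribution over \eqn{X}; a single reconstructible
#' state (\eqn{C_X = 1}) is defined as precision 1.
#'
#' @param probs Probability vector over the states of \eqn{X} (sums to at
#'   most 1).
#' @param c_x Number of states in \eqn{X}; defaults to \code{length(probs)}.
#' @return \eqn{RP_n} in \[0, 1\].
#' @export
rp_node <- function(probs, c_x = length(probs)) {
  stopifnot(c_x >= 1, all(probs >= -1e-12))
  if (sum(probs) > 1 + 1e-9) stop("probabilities sum to more than 1")
  if (c_x == 1) return(1)
  pmaxj <- max(probs)
  if (pmaxj < 1 / c_x - 1e-9) {
    stop("max probability below 1/C_X; probs are not a distribution over X")
  }
  (c_x * pmaxj - 1) / (c_x - 1)
}

#' State union across reconstructions
#'
#' The set \eqn{X} of chromosome numbers reconstructed with probability above
#' the cutoff at any node of a tree (or of several compared reconstructions),
#' which fixes the normalization constant \eqn{C_X} of \code{rp_node}.
#'
#' @param recons A reconstruction matrix (nodes x states, columns named by
#'   chromosome number) or a list of such matrices.
#' @param cutoff Probability cutoff; default \code{1e-2}.
#' @return List with \code{states} (sorted integer vector \eqn{X}) and
#'   \code{c_x}.
#' @export
build_state_union <- function(recons, cutoff = 1e-2) {
  if (is.matrix(recons)) recons <- list(recons)
  stopifnot(length(recons) >= 1L)
  states <- integer(0)
  for (r in recons) {
    hit <- apply(r > cutoff, 2L, any)
    states <- union(states, as.integer(colnames(r)[hit]))
  }
  states <- sort(states)
  list(states = states, c_x = length(states), cutoff = cutoff)
}

#' Tree-wise reconstruction precision
#'
#' Arithmetic mean of a tree's node-wise precision values.
#'
#' @param rp_values Numeric vector of \eqn{RP_n} values.
#' @return The mean.
#' @export
rp_tree <- function(rp_values) {
  stopifnot(length(rp_values) >= 1L)
  mean(rp_values)
}

#' Precision statistics of a reconstruction
#'
#' Computes per-node \eqn{RP_n} over the state union of the supplied
#' reconstructions (so values are commensurable across compared methods) and
#' the tree-wise mean \eqn{RP_t}.
#'
#' @param recon Reconstruction matrix (nodes x states).
#' @param union Optional precomputed state union (from
#'   \code{build_state_union} over the compared set); defaults to the union
#'   of \code{recon} alone.
#' @param cutoff Cutoff used when \code{union} is NULL.
#' @return List of class \code{chrom_precision}: \code{rp_n} (named by
#'   clade), \code{rp_t}, \code{range}, \code{c_x}.
#' @export
precision_stats <- function(recon, union = NULL, cutoff = 1e-2) {
  if (is.null(union)) union <- build_state_union(recon, cutoff)
  cols <- match(as.character(union$states), colnames(recon))
  if (anyNA(cols)) stop("state union contains states absent from the reconstruction")
  rp <- apply(recon[, cols, drop = FALSE], 1L, rp_node, c_x = union$c_x)
  structure(list(rp_n = rp, rp_t = rp_tree(rp), range = range(rp),
                 c_x = union$c_x), class = "chrom_precision")
}

#' Summarize a gains-minus-losses distribution
#'
#' Mean, median, range and the Chernoff mode of a sample of per-tree G-L
#' values. The Chernoff mode with bandwidth \eqn{h} is the midpoint of the
#' length-\eqn{2h} window containing the most observations; candidate window
#' centers are the data values, the midpoints of consecutive sorted values
#' and the window edges \eqn{x_i \pm h} (clamped to the data range, so the
#' maximal coverage is always attainable), and ties go to the smallest
#' center.
#'
#' @param values Numeric vector of per-tree G-L values.
#' @param mcc_value Optional G-L of the maximum clade credibility tree.
#' @param bandwidth Window half-width \eqn{h}; default 0.5.
#' @return List of class \code{chrom_gl}: \code{values}, \code{mean},
#'   \code{median}, \code{range}, \code{mode}, \code{mcc_value}.
#' @export
gl_summary <- function(values, mcc_value = NULL, bandwidth = 0.5) {
  stopifnot(length(values) >= 1L, bandwidth > 0)
  s <- sort(values)
  centers <- unique(c(s, s + bandwidth, s - bandwidth,
                      if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2))
  centers <- sort(pmin(pmax(centers, s[1L]), s[length(s)]))
  counts <- vapply(centers, function(t)
    sum(values >= t - bandwidth & values <= t + bandwidth), 0L)
  mode <- centers[which.max(counts)]   # first max = smallest center
  structure(list(values = values, mean = mean(values),
                 median = stats::median(values), range = range(values),
                 mode = mode, bandwidth = bandwidth,
                 mcc_value = mcc_value), class = "chrom_gl")
}

#' @export
print.chrom_gl <- function(x, ...) {
  cat("G-L distribution (n = ", length(x$values), "): mean ", format(x$mean),
      ", median ", format(x$median), ", mode ", format(x$mode),
      ", range [", format(x$range[1L]), ", ", format(x$range[2L]), "]",
      if (!is.null(x$mcc_value)) paste0(", MCC ", format(x$mcc_value)), "\n",
      sep = "")
  invisible(x)
}

#' Correlation of integrated and individual reconstruction precision
#'
#' For each clade, the proportion of contributing trees whose node-wise
#' precision is at or above the threshold is correlated (Pearson) with the
#' precision of the reconstruction integrated over trees. A tight
#' correlation indicates that integrated uncertainty stems from ambiguity
#' within trees rather than from conflict between unambiguous trees.
#'
#' @param integrated Named numeric vector: integrated \eqn{RP_n} per clade.
#' @param per_tree Named list (same clades): numeric vectors of per-tree
#'   \eqn{RP_n} for the trees containing the clade.
#' @param threshold Precision threshold, typically 0.90 or 0.95.
#' @return List with \code{r} (Pearson correlation, \code{NA} with a
#'   \code{note} when a vector has zero variance), \code{proportions} and
#'   \code{threshold}.
#' @export
precision_correlation <- function(integrated, per_tree, threshold = 0.95) {
  clades <- names(integrated)
  stopifnot(length(clades) >= 3L, all(clades %in% names(per_tree)))
  prop <- vapply(per_tree[clades], function(v) mean(v >= threshold), 0)
  if (stats::sd(prop) == 0 || stats::sd(integrated) == 0) {
    return(list(r = NA_real_, proportions = prop, threshold = threshold,
                note = "zero variance; correlation undefined"))
  }
  list(r = stats::cor(integrated, prop, method = "pearson"),
       proportions = prop, threshold = threshold)
}

#' MCC versus consensus precision deviation table
#'
#' Per shared clade, the ratio of the MCC tree's node-wise precision to the
#' consensus (integrated) precision, flagging deviations beyond 10 percent.
#'
#' @param consensus_rp Named numeric vector of consensus-tree \eqn{RP_n}.
#' @param mcc_rp Named numeric vector of MCC-tree \eqn{RP_n}.
#' @return A \code{data.frame} with \code{clade}, \code{consensus},
#'   \code{mcc}, \code{ratio}, \code{flag} (\code{"over"}, \code{"under"},
#'   \code{""} or \code{"undefined"}).
#' @export
mcc_deviation_table <- function(consensus_rp, mcc_rp) {
  clades <- intersect(names(consensus_rp), names(mcc_rp))
  if (length(clades) == 0L) stop("no shared clades")
  cons <- consensus_rp[clades]; mcc <- mcc_rp[clades]
  ratio <- ifelse(cons > 0, mcc / cons, NA_real_)
  flag <- ifelse(is.na(ratio), "undefined",
          ifelse(ratio >= 1.1, "over", ifelse(ratio <= 0.9, "under", "")))
  data.frame(clade = clades, consensus = unname(cons), mcc = unname(mcc),
             ratio = unname(ratio), flag = unname(flag),
             stringsAsFactors = FALSE)
}

#' Accession distance threshold
#'
#' The species-assignment threshold rule for accession filtering: the median
#' of the interspecific distances lying in the range where inter- and
#' intraspecific distances overlap, i.e. within
#' \[\code{min(inter)}, \code{max(intra)}\]. Without overlap the minimum
#' interspecific distance is returned with a \code{"no-overlap"} note (no
#' intraspecific accession then exceeds the threshold).
#'
#' @param inter Interspecific distances (from a precomputed distance matrix).
#' @param intra Intraspecific distances.
#' @return The threshold, with attribute \code{note}.
#' @export
accession_threshold <- function(inter, intra) {
  stopifnot(length(inter) >= 1L, length(intra) >= 1L)
  lo <- min(inter); hi <- max(intra)
  if (lo > hi) {
    return(structure(lo, note = "no-overlap"))
  }
  qual <- inter[inter >= lo & inter <= hi]
  structure(stats::median(qual), note = "overlap")
}
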