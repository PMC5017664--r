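#' Read a chromosome count table
#'
#' Two plain-text layouts are accepted: a TSV with taxon and integer haploid
#' count per line, and the two-line record style used by chromosome-evolution
#' software (\code{">taxon"} followed by the count on the next line).
#'
#' @param path Path to the counts file.
#' @param format \code{"tsv"}, \code{"records"} or \code{NULL} to sniff (a
#'   leading \code{">"} means records).
#' @return A named integer vector (names are taxa).
#' @export
read_counts <- function(path, format = NULL) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty counts file: ", path)
  if (is.null(format)) format <- if (startsWith(trimws(lines[1L]), ">")) "records" else "tsv"
  format <- match.arg(format, c("tsv", "records"))
  if (format == "records") {
    if (length(lines) %% 2L != 0L) stop("records format needs taxon/count line pairs")
    taxa <- sub("^>\\s*", "", lines[seq(1L, length(lines), by = 2L)])
    vals <- lines[seq(2L, length(lines), by = 2L)]
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 2L)
    if (length(bad)) stop("line ", bad[1L], " is not taxon<TAB>count")
    taxa <- vapply(parts, `[[`, "", 1L)
    vals <- vapply(parts, `[[`, "", 2L)
  }
  counts <- suppressWarnings(as.integer(vals))
  if (anyNA(counts)) stop("non-integer count for taxon ", taxa[which(is.na(counts))[1L]])
  if (anyDuplicated(taxa)) stop("duplicate taxon in counts: ", taxa[duplicated(taxa)][1L])
  stats::setNames(counts, taxa)
}

#' Write a chromosome count table
#'
#' @param counts Named integer vector.
#' @param path Output path.
#' @param format \code{"tsv"} (default) or \code{"records"}.
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(counts, path, format = c("tsv", "records")) {
  format <- match.arg(format)
  stopifnot(!is.null(names(counts)))
  lines <- if (format == "tsv") {
    paste(names(counts), counts, sep = "\t")
  } else {
    as.vector(rbind(paste0(">", names(counts)), as.character(counts)))
  }
  writeLines(lines, path)
  invisible(path)
}

check_counts <- function(counts, tree) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  missing <- setdiff(tree$tip.label, names(counts))
  if (length(missing)) {
    stop("no chromosome count for tip(s): ", paste(missing, collapse = ", "))
  }
  counts[tree$tip.label]
}
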