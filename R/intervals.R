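#' Construct a validated table of genomic intervals
#'
#' Intervals are plain data frames in the BED convention used throughout the
#' package: 0-based, half-open `[start, end)`. Conversions to the 1-based
#' closed convention of Bioconductor ranges happen only inside overlap
#' helpers, never at the API surface.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param ... further equal-length columns (e.g. `name`, `score`) carried
#'   along unchanged.
#' @param sort sort by (chrom, start, end)? Default `TRUE`.
#' @return data.frame with at least columns `chrom`, `start`, `end`.
#' @export
genomic_intervals <- function(chrom, start, end, ..., sort = TRUE) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  if (sort) df <- sort_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  if (!all(c("chrom", "start", "end") %in% names(df)))
    stop("interval table must have columns chrom, start, end")
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom) | !nzchar(df$chrom)))
    stop(what, ": chrom must be non-empty")
  if (any(!is.finite(df$start)) || any(!is.finite(df$end)))
    stop(what, ": non-finite coordinates")
  if (any(df$start < 0))
    stop(what, ": negative start coordinate")
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(what, ": start >= end (empty or inverted interval) at row ", bad[1])
  invisible(df)
}

#' @rdname genomic_intervals
#' @param df an interval data frame.
#' @export
sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

# BED (0-based half-open) -> GRanges (1-based closed). Internal only.
as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Overlapping pairs between two interval tables
#'
#' Any-overlap (>= 1 bp) join, returning the row indices of overlapping
#' pairs. Backed by [GenomicRanges::findOverlaps()].
#'
#' @param query,subject interval data frames.
#' @return data.frame with columns `query`, `subject` (row indices).
#' @keywords internal
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0)
    return(data.frame(query = integer(0), subject = integer(0)))
  # disjoint seqlevels are routine here (e.g. all domains on one chromosome)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(query), as_granges(subject)))
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}

# Per-query total overlap width in bp against a subject table.
overlap_widths <- function(query, subject) {
  out <- numeric(nrow(query))
  p <- overlap_pairs(query, subject)
  if (nrow(p)) {
    w <- pmin(query$end[p$query], subject$end[p$subject]) -
      pmax(query$start[p$query], subject$start[p$subject])
    agg <- tapply(w, p$query, sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}
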