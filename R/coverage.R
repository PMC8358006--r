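#' Run-length coverage tracks
#'
#' A coverage track is a set of non-overlapping, sorted runs
#' `(chrom, start, end, value)` plus the total mapped read count used for
#' RPKM scaling. Positions not covered by any run have value 0 — this
#' convention feeds every RPKM and methylation mean downstream.
#'
#' @param runs data.frame with columns `chrom, start, end, value`.
#' @param total_mapped total mapped reads (NA for tracks that are not
#'   read-derived, e.g. methylation beta values).
#' @param value_bounds optional `c(lo, hi)` hard bounds on values.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(runs, total_mapped = NA, value_bounds = NULL) {
  validate_intervals(runs, what = "coverage run")
  if (!"value" %in% names(runs)) stop("runs need a value column")
  if (nrow(runs) && any(!is.finite(runs$value)))
    stop("coverage values must be finite")
  if (!is.null(value_bounds) && nrow(runs)) {
    if (any(runs$value < value_bounds[1] | runs$value > value_bounds[2]))
      stop("coverage value outside bounds [", value_bounds[1], ", ",
           value_bounds[2], "]")
  }
  runs <- sort_intervals(runs)
  # overlap check: within a chromosome each run must start at or after the
  # previous run's end
  if (nrow(runs) > 1) {
    same <- runs$chrom[-1] == runs$chrom[-nrow(runs)]
    ovl <- which(same & runs$start[-1] < runs$end[-nrow(runs)])
    if (length(ovl))
      stop("overlapping bedGraph runs at ", runs$chrom[ovl[1] + 1], ":",
           runs$start[ovl[1] + 1])
  }
  idx <- lapply(split(runs, runs$chrom), function(d) {
    list(start = d$start, end = d$end, value = d$value,
         cum = c(0, cumsum(d$value * (d$end - d$start))))
  })
  structure(list(runs = runs, total_mapped = total_mapped,
                 value_bounds = value_bounds, index = idx),
            class = "coverage_track")
}

#' @rdname coverage_track
#' @param track a `coverage_track`.
#' @export
track_runs <- function(track) track$runs

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", nrow(x$runs), "runs on",
      length(x$index), "chromosomes; total_mapped =", x$total_mapped, "\n")
  invisible(x)
}

# Integral of the track value over [0, pos) on one chromosome, vectorized
# over pos. Gaps contribute 0.
track_area <- function(track, chrom, pos) {
  ix <- track$index[[chrom]]
  if (is.null(ix)) return(numeric(length(pos)))
  k <- findInterval(pos, ix$start)
  a <- ix$cum[k + 1]
  inside <- k >= 1
  if (any(inside)) {
    ki <- k[inside]
    a[inside] <- ix$cum[ki] +
      ix$value[ki] * pmax(0, pmin(pos[inside], ix$end[ki]) - ix$start[ki])
  }
  a
}

#' Sum and mean of track values over regions
#'
#' `track_region_sum` returns, per region, the sum of value x covered bp
#' (for read-depth tracks this is the read count when the value is per-base
#' depth). `track_region_mean` divides by region length, counting gaps as 0.
#'
#' @param track a [coverage_track()].
#' @param chrom,start,end equal-length region vectors (0-based half-open).
#' @return numeric vector, one entry per region.
#' @export
track_region_sum <- function(track, chrom, start, end) {
  if (any(end <= start)) stop("zero-length region")
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    out[i] <- track_area(track, ch, end[i]) - track_area(track, ch, start[i])
  }
  out
}

#' @rdname track_region_sum
#' @export
track_region_mean <- function(track, chrom, start, end) {
  track_region_sum(track, chrom, start, end) / (end - start)
}

# Mean value in n_bins equal bins across one region. Bin edges may be
# fractional; the run integral handles that exactly. Coordinates below 0
# are clamped; a fully clamped (zero-width) bin yields NA.
track_binned_means <- function(track, chrom, start, end, n_bins) {
  edges <- pmax(0, seq(start, end, length.out = n_bins + 1))
  w <- diff(edges)
  v <- diff(track_area(track, chrom, edges))
  out <- ifelse(w > 0, v / pmax(w, .Machine$double.eps), NA_real_)
  out
}
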