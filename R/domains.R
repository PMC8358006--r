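#' Parameters for silencer-domain calling
#'
#' Defaults encode the published rule set: peaks merged within 2 kb, grand
#' domains are the top 5% broadest merged domains that also exceed 50 kb,
#' narrow domains the bottom 5%, and controls a seeded 5% sample of the
#' remaining typical domains.
#'
#' @param merge_gap bp; peaks closer than this are merged (default 2000).
#' @param grand_quantile breadth quantile defining grand candidates
#'   (default 0.95).
#' @param min_breadth bp floor a grand domain must exceed (default 50000).
#' @param narrow_quantile bottom breadth quantile for narrow domains
#'   (default 0.05).
#' @param control_fraction fraction of typical domains sampled as controls
#'   (default 0.05).
#' @param seed RNG seed for the control sample.
#' @export
calling_params <- function(merge_gap = 2000, grand_quantile = 0.95,
                           min_breadth = 50000, narrow_quantile = 0.05,
                           control_fraction = 0.05, seed = 1L) {
  if (!(narrow_quantile > 0 && narrow_quantile < grand_quantile &&
        grand_quantile < 1))
    stop("need 0 < narrow_quantile < grand_quantile < 1")
  if (merge_gap < 0) stop("merge_gap must be >= 0")
  list(merge_gap = merge_gap, grand_quantile = grand_quantile,
       min_breadth = min_breadth, narrow_quantile = narrow_quantile,
       control_fraction = control_fraction, seed = as.integer(seed))
}

#' Merge peaks into domains
#'
#' Unions intervals on the same chromosome whose gap
#' (`next start - previous end`) is at most `merge_gap`; overlapping or
#' book-ended peaks always merge. Never merges across chromosomes.
#'
#' @param peaks interval data frame.
#' @param merge_gap maximum gap in bp closed by the merge.
#' @return domain data frame: `chrom, start, end, breadth, n_source_peaks`.
#' @export
merge_peaks <- function(peaks, merge_gap = 2000) {
  validate_intervals(peaks)
  if (nrow(peaks) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), breadth = numeric(0),
                      n_source_peaks = integer(0)))
  p <- sort_intervals(peaks)
  new_chrom <- c(TRUE, p$chrom[-1] != p$chrom[-nrow(p)])
  # running maximum of end within chromosome gives the current merged edge
  run_end <- p$end
  grp <- integer(nrow(p))
  g <- 0L
  edge <- -Inf
  for (i in seq_len(nrow(p))) {          # small n: domains, not reads
    if (new_chrom[i] || p$start[i] - edge > merge_gap) {
      g <- g + 1L
      edge <- p$end[i]
    } else {
      edge <- max(edge, p$end[i])
    }
    grp[i] <- g
  }
  out <- data.frame(
    chrom = tapply(p$chrom, grp, `[`, 1),
    start = as.numeric(tapply(p$start, grp, min)),
    end = as.numeric(tapply(p$end, grp, max)),
    n_source_peaks = as.integer(tapply(p$start, grp, length)),
    stringsAsFactors = FALSE)
  stopifnot(all(tapply(p$chrom, grp, function(ch) length(unique(ch))) == 1))
  out$breadth <- out$end - out$start
  rownames(out) <- NULL
  sort_intervals(out[, c("chrom", "start", "end", "breadth", "n_source_peaks")])
}

#' Input-subtracted RPKM signal over regions
#'
#' `RPKM = reads_in_region / (length_kb * millions_mapped)` where
#' `reads_in_region` is the integral of the per-base depth over the region;
#' the result is treatment RPKM minus input RPKM, floored at 0 (negative
#' enrichment has no downstream interpretation).
#'
#' @param regions interval data frame (e.g. domains or extended gene bodies).
#' @param treatment,input [coverage_track()]s with `total_mapped` set.
#' @return numeric vector of signal values (>= 0), one per region.
#' @export
quantify_domain_signal <- function(regions, treatment, input) {
  validate_intervals(regions)
  if (!is.finite(treatment$total_mapped) || treatment$total_mapped <= 0)
    stop("treatment track needs total_mapped > 0")
  if (!is.finite(input$total_mapped) || input$total_mapped <= 0)
    stop("input track needs total_mapped > 0")
  len_kb <- (regions$end - regions$start) / 1000
  rpkm_t <- track_region_sum(treatment, regions$chrom, regions$start,
                             regions$end) /
    (len_kb * treatment$total_mapped / 1e6)
  rpkm_i <- track_region_sum(input, regions$chrom, regions$start,
                             regions$end) /
    (len_kb * input$total_mapped / 1e6)
  pmax(0, rpkm_t - rpkm_i)
}

#' Classify domains by breadth quantile
#'
#' Grand: breadth at or above the empirical `grand_quantile` AND strictly
#' above `min_breadth`, capped at `ceiling((1 - grand_quantile) * n)` by the
#' tie-break (breadth desc, signal desc, chrom, start). Narrow: bottom
#' `narrow_quantile` analogously (breadth asc). Control: a seeded uniform
#' sample of `control_fraction` of the typical (neither grand nor narrow)
#' domains, kept as an overlay flag.
#'
#' @param domains domain data frame from [merge_peaks()], optionally with a
#'   `signal` column (used in the tie-break; 0 when absent).
#' @param params a [calling_params()] list.
#' @return `domains` with `class_label` in grand/typical/narrow and logical
#'   `is_control`; attribute `"thresholds"` carries the realized cut-offs.
#' @export
classify_domains <- function(domains, params = calling_params()) {
  n <- nrow(domains)
  if (n == 0) stop("no domains to classify")
  if (n < 20)
    warning("fewer than 20 domains; breadth quantiles are unstable")
  sig <- if ("signal" %in% names(domains)) domains$signal else numeric(n)
  b <- domains$breadth
  grand_cut <- as.numeric(stats::quantile(b, params$grand_quantile))
  narrow_cut <- as.numeric(stats::quantile(b, params$narrow_quantile))
  # round before ceiling: (1 - 0.95) * 100 is 5 + 4e-15 in floating point
  cap_grand <- ceiling(round((1 - params$grand_quantile) * n, 9))
  cap_narrow <- ceiling(round(params$narrow_quantile * n, 9))

  ord_desc <- order(-b, -sig, domains$chrom, domains$start)
  cand <- ord_desc[b[ord_desc] >= grand_cut & b[ord_desc] > params$min_breadth]
  if (length(cand) > cap_grand) {
    warning("breadth ties at the grand cut-off; capping at ", cap_grand,
            " domains by tie-break")
    cand <- cand[seq_len(cap_grand)]
  }
  grand_idx <- cand

  ord_asc <- order(b, sig, domains$chrom, domains$start)
  candn <- ord_asc[b[ord_asc] <= narrow_cut]
  candn <- setdiff(candn, grand_idx)
  if (length(candn) > cap_narrow) {
    warning("breadth ties at the narrow cut-off; capping at ", cap_narrow)
    candn <- candn[seq_len(cap_narrow)]
  }
  narrow_idx <- candn

  lab <- rep("typical", n)
  lab[grand_idx] <- "grand"
  lab[narrow_idx] <- "narrow"
  typical_idx <- which(lab == "typical")
  n_ctrl <- round(params$control_fraction * n)
  ctrl <- logical(n)
  if (n_ctrl > 0 && length(typical_idx) > 0) {
    ctrl[local_seed(params$seed,
                    sample(typical_idx, min(n_ctrl, length(typical_idx))))] <- TRUE
  }
  domains$domain_id <- sprintf("D%05d", seq_len(n))
  domains$signal <- sig
  domains$class_label <- lab
  domains$is_control <- ctrl
  attr(domains, "thresholds") <- data.frame(
    grand_breadth_cut = grand_cut, narrow_breadth_cut = narrow_cut,
    min_breadth = params$min_breadth,
    n = n, n_grand = length(grand_idx), n_narrow = length(narrow_idx),
    n_control = sum(ctrl))
  domains
}

# Evaluate `expr` under a locally seeded, platform-pinned RNG without
# touching the caller's RNG state.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Breadth-normalized metagene matrix over domains
#'
#' Each row covers one domain: `flank_bins` fixed-width bins over the
#' `flank` bp upstream, `body_bins` bins over the body rescaled to a common
#' width regardless of breadth, and `flank_bins` bins downstream. Bin value
#' is the mean track value (gaps count 0). Flanks running off the
#' chromosome start are truncated; fully truncated bins are NA and the
#' affected domains recorded in the `"truncated"` attribute.
#'
#' @param domains domain data frame.
#' @param track a [coverage_track()].
#' @param flank bp of flank each side (default 3000).
#' @param body_bins,flank_bins bin counts (defaults 50 and 10).
#' @return matrix `(n_domains, 2 * flank_bins + body_bins)` with the mean
#'   profile in attribute `"mean_profile"`.
#' @export
metagene_matrix <- function(domains, track, flank = 3000, body_bins = 50,
                            flank_bins = 10) {
  if (nrow(domains) == 0) stop("no domains for metagene profile")
  if (body_bins < 3) stop("need body_bins >= 3")
  ncol_out <- 2 * flank_bins + body_bins
  m <- matrix(NA_real_, nrow(domains), ncol_out)
  truncated <- logical(nrow(domains))
  for (i in seq_len(nrow(domains))) {
    ch <- domains$chrom[i]; s <- domains$start[i]; e <- domains$end[i]
    left <- track_binned_means(track, ch, s - flank, s, flank_bins)
    body <- track_binned_means(track, ch, s, e, body_bins)
    right <- track_binned_means(track, ch, e, e + flank, flank_bins)
    truncated[i] <- anyNA(left)
    m[i, ] <- c(left, body, right)
  }
  attr(m, "mean_profile") <- colMeans(m, na.rm = TRUE)
  attr(m, "truncated") <- which(truncated)
  m
}

#' Write classified domains as BED6
#'
#' name = class label (controls as `control`), score = signal x 10 rounded.
#' @param domains classified domain data frame.
#' @param path destination.
#' @export
write_domains_bed <- function(domains, path) {
  df <- domains
  df$name <- ifelse(df$is_control, "control", df$class_label)
  df$score <- round(df$signal * 10)
  df$strand <- "."
  write_bed(df[, c("chrom", "start", "end", "name", "score", "strand")], path)
}
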