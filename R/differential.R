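#' Strand-oriented binned coverage profile over genes
#'
#' Per gene: `flank_bins` bins over the `flank` bp upstream of the 5' end,
#' `body_bins` equal bins over the body, `flank_bins` bins downstream.
#' Minus-strand genes are reversed so column 1 is always 5'.
#'
#' @param genes gene models.
#' @param track a [coverage_track()].
#' @param body_bins,flank,flank_bins geometry (defaults 50, 2000, 10).
#' @return matrix `(n_genes, 2 * flank_bins + body_bins)`, rownames gene_id;
#'   mean profile in attribute `"mean_profile"`.
#' @export
gene_binned_profile <- function(genes, track, body_bins = 50, flank = 2000,
                                flank_bins = 10) {
  short <- genes$end - genes$start < body_bins
  if (any(short))
    warning(sum(short), " gene(s) shorter than body_bins bp; bins are sub-bp")
  m <- matrix(NA_real_, nrow(genes), 2 * flank_bins + body_bins,
              dimnames = list(genes$gene_id, NULL))
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]; s <- genes$start[i]; e <- genes$end[i]
    v <- c(track_binned_means(track, ch, s - flank, s, flank_bins),
           track_binned_means(track, ch, s, e, body_bins),
           track_binned_means(track, ch, e, e + flank, flank_bins))
    if (genes$strand[i] == "-") v <- rev(v)
    m[i, ] <- v
  }
  attr(m, "mean_profile") <- colMeans(m, na.rm = TRUE)
  m
}

#' Gene-level H3K27me3 signal (body +/- extension)
#'
#' Input-subtracted RPKM over the gene body extended both sides, via
#' [quantify_domain_signal()].
#'
#' @param genes gene models.
#' @param treatment,input condition-specific [coverage_track()]s.
#' @param extension bp each side (default 2000).
#' @return numeric vector named by gene_id.
#' @export
gene_k27_signal <- function(genes, treatment, input, extension = 2000) {
  reg <- data.frame(chrom = genes$chrom,
                    start = pmax(0, genes$start - extension),
                    end = genes$end + extension)
  stats::setNames(quantify_domain_signal(reg, treatment, input),
                  genes$gene_id)
}

#' Classify per-gene H3K27me3 loss/gain between two conditions
#'
#' `log2_signal_fc = log2((tumor + pc) / (normal + pc))`; loss when below
#' `-fold_threshold`, gain when above `+fold_threshold`, else stable. The
#' default threshold of 1 log2 unit encodes the "> 1-fold" (2x) rule; the
#' pseudocount regularizes near-zero RPKM.
#'
#' @param signal_normal,signal_tumor numeric vectors named by gene_id
#'   (RPKM, >= 0).
#' @param pseudocount RPKM pseudocount (default 0.25).
#' @param fold_threshold log2 threshold (default 1.0).
#' @return data.frame: `gene_id, signal_normal, signal_tumor,
#'   log2_signal_fc, k27_class`.
#' @export
classify_h3k27me3_change <- function(signal_normal, signal_tumor,
                                     pseudocount = 0.25,
                                     fold_threshold = 1.0) {
  if (length(signal_normal) != length(signal_tumor))
    stop("condition signal vectors differ in length")
  if (any(signal_normal < 0) || any(signal_tumor < 0))
    stop("signals must be >= 0 (floored upstream)")
  ids <- names(signal_normal)
  if (is.null(ids)) ids <- as.character(seq_along(signal_normal))
  fc <- log2((signal_tumor + pseudocount) / (signal_normal + pseudocount))
  cls <- ifelse(fc < -fold_threshold, "loss",
                ifelse(fc > fold_threshold, "gain", "stable"))
  data.frame(gene_id = ids, signal_normal = unname(signal_normal),
             signal_tumor = unname(signal_tumor),
             log2_signal_fc = unname(fc), k27_class = cls,
             stringsAsFactors = FALSE)
}

#' Integrate H3K27me3 change with differential expression
#'
#' External mode takes a precomputed DE table (`gene_id, log2fc, fdr`, e.g.
#' from DESeq2). Internal mode derives one from replicate expression values
#' with a per-gene rank-sum test and BH-FDR — only meant for synthetic
#' runs. Activation classes: `activated` = loss & log2fc > `de_lfc` & fdr <
#' `de_fdr`; `silenced` = gain & log2fc < -`de_lfc` & fdr < `de_fdr`;
#' otherwise `loss_only`/`gain_only`/`stable`. Genes absent from the DE
#' table keep the k27-only label.
#'
#' @param k27 output of [classify_h3k27me3_change()].
#' @param de_table data.frame `gene_id, log2fc, fdr` (external mode).
#' @param replicate_counts matrix (genes x samples, rownames gene_id) for
#'   internal mode.
#' @param condition factor/character of length `ncol(replicate_counts)`
#'   with two levels, normal first.
#' @param de_lfc,de_fdr significance gates (defaults 1 and 0.05).
#' @return data.frame of per-gene differential calls.
#' @export
integrate_expression_changes <- function(k27, de_table = NULL,
                                         replicate_counts = NULL,
                                         condition = NULL,
                                         de_lfc = 1, de_fdr = 0.05) {
  if (is.null(de_table)) {
    if (is.null(replicate_counts) || is.null(condition))
      stop("need either de_table or replicate_counts + condition")
    de_table <- internal_de_table(replicate_counts, condition)
  }
  if (anyDuplicated(de_table$gene_id)) {
    dup <- de_table[de_table$gene_id %in%
                      de_table$gene_id[duplicated(de_table$gene_id)], ]
    if (nrow(unique(dup)) != length(unique(dup$gene_id)))
      stop("conflicting duplicate gene rows in DE table")
    de_table <- de_table[!duplicated(de_table$gene_id), ]
  }
  i <- match(k27$gene_id, de_table$gene_id)
  calls <- k27
  calls$expr_log2fc <- de_table$log2fc[i]
  calls$expr_fdr <- de_table$fdr[i]
  up <- !is.na(calls$expr_log2fc) & calls$expr_log2fc > de_lfc &
    !is.na(calls$expr_fdr) & calls$expr_fdr < de_fdr
  down <- !is.na(calls$expr_log2fc) & calls$expr_log2fc < -de_lfc &
    !is.na(calls$expr_fdr) & calls$expr_fdr < de_fdr
  calls$activation_class <- ifelse(
    calls$k27_class == "loss", ifelse(up, "activated", "loss_only"),
    ifelse(calls$k27_class == "gain", ifelse(down, "silenced", "gain_only"),
           "stable"))
  calls
}

# Per-gene rank-sum DE on replicate expression values; synthetic-run
# convenience, not a DESeq2 substitute.
internal_de_table <- function(replicate_counts, condition, pseudo = 0.5) {
  condition <- as.factor(condition)
  if (nlevels(condition) != 2) stop("condition needs exactly 2 levels")
  a <- levels(condition)[1]; b <- levels(condition)[2]
  xa <- replicate_counts[, condition == a, drop = FALSE]
  xb <- replicate_counts[, condition == b, drop = FALSE]
  p <- vapply(seq_len(nrow(replicate_counts)), function(i)
    mann_whitney(xb[i, ], xa[i, ], "two-sided")$p_value, 0)
  data.frame(gene_id = rownames(replicate_counts),
             log2fc = log2((rowMeans(xb) + pseudo) / (rowMeans(xa) + pseudo)),
             fdr = bh_fdr(p), stringsAsFactors = FALSE)
}

#' Activation percentages from class counts
#'
#' Self-consistent percentages of the loss/gain/activation bookkeeping:
#' loss and gain as a share of all considered genes, activation as a share
#' of loss genes, silencing as a share of gain genes. Rounded to 1 decimal.
#'
#' @param n_total,n_loss,n_gain,n_activated,n_silenced integer counts.
#' @export
activation_percentages <- function(n_total, n_loss, n_gain, n_activated,
                                   n_silenced) {
  stopifnot(n_loss + n_gain <= n_total, n_activated <= n_loss,
            n_silenced <= n_gain)
  pct <- function(num, den) if (den > 0) round(100 * num / den, 1) else 0
  list(n_total = n_total, n_loss = n_loss, n_gain = n_gain,
       n_activated = n_activated, n_silenced = n_silenced,
       loss_pct = pct(n_loss, n_total), gain_pct = pct(n_gain, n_total),
       activated_of_loss_pct = pct(n_activated, n_loss),
       silenced_of_gain_pct = pct(n_silenced, n_gain))
}

#' Summarize differential calls for a gene set
#'
#' Counts and percentages via [activation_percentages()], Spearman of
#' H3K27me3 log2 fold-change vs expression log2 fold-change, a rank-sum
#' shift test of activated-gene expression changes against a background,
#' and a cumulative-distribution table of expression changes.
#'
#' @param calls output of [integrate_expression_changes()], usually
#'   restricted to one domain class's marked genes.
#' @param background_log2fc numeric vector of background expression
#'   log2 fold-changes (optional).
#' @return list: `percentages`, `correlation` (r, p or NULL), `shift_test`
#'   (or NULL), `cumulative` (sorted log2fc + cumulative fraction).
#' @export
activation_summary <- function(calls, background_log2fc = NULL) {
  pc <- activation_percentages(
    n_total = nrow(calls),
    n_loss = sum(calls$k27_class == "loss"),
    n_gain = sum(calls$k27_class == "gain"),
    n_activated = sum(calls$activation_class == "activated"),
    n_silenced = sum(calls$activation_class == "silenced"))
  ok <- !is.na(calls$expr_log2fc)
  corr <- NULL
  if (sum(ok) >= 3 && stats::sd(calls$log2_signal_fc[ok]) > 0 &&
      stats::sd(calls$expr_log2fc[ok]) > 0)
    corr <- rank_correlation(calls$log2_signal_fc[ok], calls$expr_log2fc[ok],
                             "spearman")
  shift <- NULL
  act <- calls$expr_log2fc[calls$activation_class == "activated" & ok]
  if (!is.null(background_log2fc) && length(act) >= 1 &&
      length(background_log2fc) >= 1)
    shift <- mann_whitney(act, background_log2fc, "greater")
  x <- sort(calls$expr_log2fc[ok])
  cumulative <- if (length(x))
    data.frame(expr_log2fc = x, cum_fraction = seq_along(x) / length(x))
  else NULL
  list(percentages = pc, correlation = corr, shift_test = shift,
       cumulative = cumulative)
}

#' Mark and methylation profiles around a gene set
#'
#' For each mark and condition, the mean strand-oriented profile from
#' `upstream` bp before the TSS to `downstream` bp past the TES (body
#' rescaled to `body_bins`). Methylation deltas (tumor - normal beta) are
#' computed separately for the promoter (TSS +/- `promoter_halfwidth`) and
#' the gene body (TSS + halfwidth .. TES), with a per-set flag for
#' "gene-body hypermethylation without promoter hypomethylation".
#'
#' @param genes gene models for the set of interest (e.g. activated genes).
#' @param tracks nested list `tracks[[mark]][[condition]]` of coverage
#'   tracks; conditions `"normal"` and `"tumor"`.
#' @param methylation list with `normal` and `tumor` beta-value tracks
#'   (optional).
#' @param upstream,downstream bp (defaults 5000 and 10000).
#' @param body_bins,upstream_bins,downstream_bins bin counts.
#' @param promoter_halfwidth promoter half-width in bp (default 2000).
#' @param hypo_tolerance promoter delta above `-hypo_tolerance` still
#'   counts as "not hypomethylated" (default 0.01).
#' @return list: `profiles[[mark]][[condition]]` mean profiles,
#'   `methylation` (per-gene deltas, set means, flag) or NULL.
#' @export
region_mark_profiles <- function(genes, tracks, methylation = NULL,
                                 upstream = 5000, downstream = 10000,
                                 body_bins = 50, upstream_bins = 10,
                                 downstream_bins = 20,
                                 promoter_halfwidth = 2000,
                                 hypo_tolerance = 0.01) {
  prof_one <- function(track) {
    m <- matrix(NA_real_, nrow(genes), upstream_bins + body_bins + downstream_bins)
    for (i in seq_len(nrow(genes))) {
      ch <- genes$chrom[i]
      minus <- genes$strand[i] == "-"
      s <- genes$start[i]; e <- genes$end[i]
      up <- if (minus) track_binned_means(track, ch, e, e + upstream, upstream_bins)
            else track_binned_means(track, ch, s - upstream, s, upstream_bins)
      body <- track_binned_means(track, ch, s, e, body_bins)
      dn <- if (minus) track_binned_means(track, ch, s - downstream, s, downstream_bins)
            else track_binned_means(track, ch, e, e + downstream, downstream_bins)
      v <- c(if (minus) rev(up) else up,
             if (minus) rev(body) else body,
             if (minus) rev(dn) else dn)
      m[i, ] <- v
    }
    colMeans(m, na.rm = TRUE)
  }
  profiles <- lapply(tracks, function(cond_tracks) {
    missing <- setdiff(c("normal", "tumor"), names(cond_tracks))
    if (length(missing)) {
      warning("mark missing condition(s): ", paste(missing, collapse = ", "),
              "; skipped")
      return(NULL)
    }
    lapply(cond_tracks, prof_one)
  })
  meth <- NULL
  if (!is.null(methylation)) {
    tss <- genes$tss
    prom_s <- pmax(0, tss - promoter_halfwidth)
    prom_e <- tss + promoter_halfwidth
    body_s <- pmax(0, ifelse(genes$strand == "-",
                             genes$start, genes$start + promoter_halfwidth))
    body_e <- ifelse(genes$strand == "-",
                     genes$end - promoter_halfwidth, genes$end)
    bad <- body_e <= body_s   # genes shorter than the promoter half-width
    body_s[bad] <- genes$start[bad]; body_e[bad] <- genes$end[bad]
    mm <- function(track, s, e) track_region_mean(track, genes$chrom, s, e)
    d_prom <- mm(methylation$tumor, prom_s, prom_e) -
      mm(methylation$normal, prom_s, prom_e)
    d_body <- mm(methylation$tumor, body_s, body_e) -
      mm(methylation$normal, body_s, body_e)
    meth <- list(
      per_gene = data.frame(gene_id = genes$gene_id,
                            delta_promoter = d_prom, delta_body = d_body),
      mean_delta_promoter = mean(d_prom), mean_delta_body = mean(d_body),
      body_hyper_no_promoter_hypo =
        mean(d_body) > 0 && mean(d_prom) > -hypo_tolerance)
  }
  list(profiles = profiles, methylation = meth)
}
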