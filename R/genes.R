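#' Map domains to the genes they mark
#'
#' A gene is marked by a domain when the domain overlaps the gene body
#' extended by `extension` bp on both sides (any overlap of >= 1 bp,
#' half-open). The best domain per gene is the broadest overlapping one;
#' the gene inherits its class.
#'
#' @param domains classified domain data frame (needs `breadth`,
#'   `class_label`, `is_control`, `domain_id`).
#' @param genes gene models from [read_gene_table()]/[make_gene_models()].
#' @param extension bp added each side of the gene body (default 2000).
#' @return data.frame, one row per gene: `gene_id, chrom, strand, marked,
#'   mark_breadth` (0 when unmarked), `class` (class of the best domain or
#'   "none"), `is_control`, `best_domain`, `n_domains`.
#' @export
map_domains_to_genes <- function(domains, genes, extension = 2000) {
  ext <- data.frame(chrom = genes$chrom,
                    start = pmax(0, genes$start - extension),
                    end = genes$end + extension)
  p <- overlap_pairs(ext, domains)
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    strand = genes$strand, marked = FALSE,
                    mark_breadth = 0, class = "none",
                    is_control = FALSE, best_domain = NA_character_,
                    n_domains = 0L, stringsAsFactors = FALSE)
  if (nrow(p)) {
    # best domain per gene = max breadth; deterministic tie-break on start
    ord <- order(p$query, -domains$breadth[p$subject],
                 domains$start[p$subject])
    p <- p[ord, ]
    best <- p[!duplicated(p$query), ]
    out$marked[best$query] <- TRUE
    out$mark_breadth[best$query] <- domains$breadth[best$subject]
    out$class[best$query] <- domains$class_label[best$subject]
    out$is_control[best$query] <- domains$is_control[best$subject]
    out$best_domain[best$query] <- domains$domain_id[best$subject]
    cnt <- table(p$query)
    out$n_domains[as.integer(names(cnt))] <- as.integer(cnt)
  }
  out
}

#' Constraint (missense Z, dN/dS) along the breadth continuum
#'
#' Summarizes marked genes in breadth-quantile bins and tests grand-marked
#' genes against all other marked genes with the rank-sum test, for both
#' constraint metrics. Expected directions under the silencer-domain model:
#' grand-marked genes have larger missense Z (more constrained) and smaller
#' dN/dS (more conserved).
#'
#' @param marks output of [map_domains_to_genes()].
#' @param constraints data.frame `gene_id, missense_z, dn_ds` (NAs allowed).
#' @param n_bins breadth-quantile bins for the per-bin summary (default 10).
#' @return list: `bin_summary` (per-bin medians), `tests` (per metric:
#'   statistic, p, direction of the grand median).
#' @export
constraint_association <- function(marks, constraints, n_bins = 10) {
  m <- merge(marks[marks$marked, ], constraints, by = "gene_id")
  if (nrow(m) < 6) stop("too few marked genes with constraint data")
  m$bin <- breadth_bins(m$mark_breadth, n_bins)
  bin_summary <- do.call(rbind, lapply(split(m, m$bin), function(d)
    data.frame(bin = d$bin[1], n = nrow(d),
               median_breadth = stats::median(d$mark_breadth),
               median_missense_z = stats::median(d$missense_z, na.rm = TRUE),
               median_dn_ds = stats::median(d$dn_ds, na.rm = TRUE))))
  rownames(bin_summary) <- NULL
  grand <- m$class == "grand"
  if (!any(grand) || all(grand))
    stop("need both grand-marked and other marked genes")
  tests <- lapply(c(missense_z = "missense_z", dn_ds = "dn_ds"), function(col) {
    gx <- m[[col]][grand & !is.na(m[[col]])]
    ox <- m[[col]][!grand & !is.na(m[[col]])]
    if (length(gx) < 3 || length(ox) < 3)
      stop("all genes missing metric: ", col)
    tr <- mann_whitney(gx, ox, "two-sided")
    tr$direction <- if (stats::median(gx) > stats::median(ox))
      "grand_greater" else "grand_less"
    tr
  })
  list(bin_summary = bin_summary, tests = tests)
}

# Equal-count quantile bins (1 = narrowest marks, n_bins = broadest).
breadth_bins <- function(breadth, n_bins) {
  r <- rank(breadth, ties.method = "first")
  as.integer(ceiling(r * n_bins / length(breadth)))
}

#' Breadth vs expression trend over marked genes
#'
#' Bins marked genes into `n_bins` equal-count bins by mark breadth and
#' correlates bin index with the bin median TPM (Spearman). A negative r
#' recovers breadth-dependent repression.
#'
#' @param marks output of [map_domains_to_genes()].
#' @param expression data.frame with `gene_id` and `tpm`.
#' @param n_bins number of equal-count breadth bins (default 20, >= 5).
#' @return list: `bin_table` (bin, n, median_breadth, median_tpm), `r`, `p`.
#' @export
breadth_expression_trend <- function(marks, expression, n_bins = 20) {
  if (n_bins < 5) stop("need n_bins >= 5")
  m <- merge(marks[marks$marked, ], expression, by = "gene_id")
  if (nrow(m) < n_bins) stop("fewer marked genes than bins")
  m$bin <- breadth_bins(m$mark_breadth, n_bins)
  tab <- do.call(rbind, lapply(split(m, m$bin), function(d)
    data.frame(bin = d$bin[1], n = nrow(d),
               median_breadth = stats::median(d$mark_breadth),
               median_tpm = stats::median(d$tpm))))
  rownames(tab) <- NULL
  ct <- rank_correlation(tab$bin, tab$median_tpm, "spearman")
  list(bin_table = tab, r = ct$r, p = ct$p)
}
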