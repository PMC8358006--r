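## Relating silencer domains to 3D-genome annotations: TAD census and
## position profile, loop connectivity and multiplexity, a length- and
## chromosome-preserving permutation null, loop-target genes, and the
## enrichment-correlation comparison of two gene sets.

anchors_of <- function(loops) {
  n <- nrow(loops)
  data.frame(chrom = c(loops$chrom1, loops$chrom2),
             start = c(loops$start1, loops$start2),
             end = c(loops$end1, loops$end2),
             loop_id = rep(seq_len(n), 2),
             side = rep(1:2, each = n),
             stringsAsFactors = FALSE)
}

check_tads_partition <- function(tads) {
  t <- sort_intervals(tads)
  if (nrow(t) > 1) {
    same <- t$chrom[-1] == t$chrom[-nrow(t)]
    if (any(same & t$start[-1] < t$end[-nrow(t)]))
      stop("overlapping TADs; expected a per-chromosome partition")
  }
  t
}

#' TAD overlap census per domain class
#'
#' For each domain: does it overlap any TAD (>= 1 bp), does it overlap any
#' loop anchor, and does it cover at least `coverage_threshold` of some
#' TAD's length ("spans the entirety of a TAD").
#'
#' @param domains classified domain data frame.
#' @param tads interval data frame; must be non-overlapping per chromosome.
#' @param loops loop data frame from [read_bedpe()].
#' @param coverage_threshold fraction of a TAD a domain must cover to count
#'   as spanning it (default 0.9).
#' @return list: `relations` (per-domain flags + `covered_fraction_of_tad`),
#'   `census` (per class: n, counts and fractions of each flag).
#' @export
tad_overlap_summary <- function(domains, tads, loops,
                                coverage_threshold = 0.9) {
  tads <- check_tads_partition(tads)
  n <- nrow(domains)
  rel <- data.frame(domain_id = domains$domain_id,
                    class = domains$class_label,
                    is_control = domains$is_control,
                    overlaps_tad = FALSE, marks_anchor = FALSE,
                    spans_entire_tad = FALSE,
                    covered_fraction_of_tad = 0)
  p <- overlap_pairs(domains, tads)
  if (nrow(p)) {
    rel$overlaps_tad[unique(p$query)] <- TRUE
    ov <- pmin(domains$end[p$query], tads$end[p$subject]) -
      pmax(domains$start[p$query], tads$start[p$subject])
    frac <- ov / (tads$end[p$subject] - tads$start[p$subject])
    mx <- tapply(frac, p$query, max)
    rel$covered_fraction_of_tad[as.integer(names(mx))] <- as.numeric(mx)
    rel$spans_entire_tad <- rel$covered_fraction_of_tad >= coverage_threshold
  }
  if (nrow(loops)) {
    pa <- overlap_pairs(anchors_of(loops), domains)
    rel$marks_anchor[unique(pa$subject)] <- TRUE
  }
  census <- do.call(rbind, lapply(domain_class_sets(domains), function(idx) {
    d <- rel[idx, ]
    data.frame(n = nrow(d),
               n_overlap_tad = sum(d$overlaps_tad),
               frac_overlap_tad = mean(d$overlaps_tad),
               n_marks_anchor = sum(d$marks_anchor),
               frac_marks_anchor = mean(d$marks_anchor),
               n_spans_tad = sum(d$spans_entire_tad),
               frac_spans_tad = mean(d$spans_entire_tad))
  }))
  census <- cbind(class = rownames(census), census)
  rownames(census) <- NULL
  list(relations = rel, census = census)
}

# The three disjoint comparison sets of the breadth analysis, plus typical.
domain_class_sets <- function(domains) {
  list(grand = which(domains$class_label == "grand"),
       typical = which(domains$class_label == "typical"),
       narrow = which(domains$class_label == "narrow"),
       control = which(domains$is_control))
}

#' Domain positions across normalized TADs
#'
#' Each domain is assigned to the TAD of maximal overlap; its normalized
#' position is `2 * (domain_mid - tad_mid) / tad_length`, clipped to
#' `[-1, 1]` (0 = TAD center, +/-1 = boundaries). Per-class histograms are
#' normalized to unit area.
#'
#' @inheritParams tad_overlap_summary
#' @param n_bins histogram bins over `[-1, 1]` (default 20).
#' @return list: `positions` (per assigned domain), `profile` (long table
#'   class/bin_mid/density), `n_excluded` (domains overlapping no TAD).
#' @export
tad_position_profile <- function(domains, tads, n_bins = 20) {
  tads <- check_tads_partition(tads)
  p <- overlap_pairs(domains, tads)
  if (nrow(p) == 0)
    return(list(positions = NULL, profile = NULL, n_excluded = nrow(domains)))
  ov <- pmin(domains$end[p$query], tads$end[p$subject]) -
    pmax(domains$start[p$query], tads$start[p$subject])
  p <- p[order(p$query, -ov, p$subject), ]
  best <- p[!duplicated(p$query), ]
  dmid <- (domains$start[best$query] + domains$end[best$query]) / 2
  tmid <- (tads$start[best$subject] + tads$end[best$subject]) / 2
  tlen <- tads$end[best$subject] - tads$start[best$subject]
  pos <- pmin(1, pmax(-1, 2 * (dmid - tmid) / tlen))
  positions <- data.frame(domain_id = domains$domain_id[best$query],
                          class = domains$class_label[best$query],
                          is_control = domains$is_control[best$query],
                          position = pos)
  breaks <- seq(-1, 1, length.out = n_bins + 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  sets <- domain_class_sets(domains)
  profile <- do.call(rbind, lapply(names(sets), function(cl) {
    x <- positions$position[best$query %in% sets[[cl]]]
    if (!length(x)) return(NULL)
    h <- hist(x, breaks = breaks, plot = FALSE)
    data.frame(class = cl, bin_mid = mids, density = h$density)
  }))
  list(positions = positions, profile = profile,
       n_excluded = nrow(domains) - nrow(positions))
}

# Per-loop domain hits for a domain set: which domains overlap each anchor.
loop_domain_hits <- function(doms, loops) {
  a <- anchors_of(loops)
  p <- overlap_pairs(a, doms)
  if (!nrow(p))
    return(list())
  split(data.frame(side = a$side[p$query], dom = p$subject,
                   anchor = p$query),
        a$loop_id[p$query])
}

# Core connectivity: a domain is connected iff some loop has one anchor
# overlapping it and the other anchor overlapping a DIFFERENT domain of the
# set (self-loops excluded). Returns per-domain connected flag and distinct
# partner-anchor count (anchors reached via loops touching the domain,
# excluding anchors overlapping the domain itself).
connectivity_core <- function(doms, loops) {
  n <- nrow(doms)
  connected <- logical(n)
  partners <- vector("list", n)
  hits <- loop_domain_hits(doms, loops)
  a <- anchors_of(loops)
  akey <- paste(a$chrom, a$start, a$end)
  for (h in hits) {
    s1 <- unique(h$dom[h$side == 1]); s2 <- unique(h$dom[h$side == 2])
    a1 <- unique(h$anchor[h$side == 1]); a2 <- unique(h$anchor[h$side == 2])
    if (length(s1) && length(s2)) {
      for (d in s1) if (any(s2 != d)) connected[d] <- TRUE
      for (d in s2) if (any(s1 != d)) connected[d] <- TRUE
    }
    # partner anchors: other side's anchors not overlapping the domain itself
    loop_id <- if (length(a1)) a$loop_id[a1[1]] else a$loop_id[a2[1]]
    other1 <- nrow(loops) + loop_id   # row index of side-2 anchor in `a`
    other2 <- loop_id                 # side-1 anchor
    for (d in s1) if (!d %in% s2) partners[[d]] <- c(partners[[d]], akey[other1])
    for (d in s2) if (!d %in% s1) partners[[d]] <- c(partners[[d]], akey[other2])
  }
  data.frame(connected = connected,
             partner_anchor_count = vapply(partners,
                                           function(x) length(unique(x)), 0L))
}

#' Loop connectivity and multiplexity per domain class
#'
#' Connectivity is within-class: a grand domain counts as connected only
#' when a loop joins it to another grand domain, and likewise for narrow
#' and control sets. Multiplexity buckets the per-domain count of distinct
#' partner anchors into 1, 2, >= 3.
#'
#' @param domains classified domain data frame.
#' @param loops loop data frame.
#' @param classes which class sets to profile.
#' @return named list per class: `n`, `connected_fraction`, `per_domain`,
#'   `multiplexity` (counts over buckets `1`, `2`, `>=3`).
#' @export
interaction_connectivity <- function(domains, loops,
                                     classes = c("grand", "narrow", "control")) {
  sets <- domain_class_sets(domains)[classes]
  lapply(sets, function(idx) {
    d <- domains[idx, , drop = FALSE]
    if (nrow(d) == 0)
      return(list(n = 0L, connected_fraction = NA_real_, per_domain = NULL,
                  multiplexity = c(`1` = 0L, `2` = 0L, `>=3` = 0L)))
    cc <- connectivity_core(d, loops)
    cc$domain_id <- d$domain_id
    k <- cc$partner_anchor_count[cc$partner_anchor_count >= 1]
    list(n = nrow(d), connected_fraction = mean(cc$connected),
         per_domain = cc,
         multiplexity = c(`1` = sum(k == 1), `2` = sum(k == 2),
                          `>=3` = sum(k >= 3)))
  })
}

# Prebuilt per-chromosome anchor index for the permutation hot loop. The
# shuffle recomputes the connected count ~10^3 times, so the inner overlap
# search is plain findInterval on sorted anchor starts rather than a
# GRanges construction per iteration.
anchor_index <- function(loops) {
  a <- anchors_of(loops)
  idx <- lapply(split(seq_len(nrow(a)), a$chrom), function(ix) {
    o <- ix[order(a$start[ix])]
    list(start = a$start[o], end = a$end[o], row = o,
         maxw = max(a$end[o] - a$start[o]))
  })
  list(idx = idx, loop_id = a$loop_id, side = a$side, n_loops = nrow(loops))
}

count_connected_ai <- function(chrom, start, end, ai) {
  n <- length(chrom)
  if (n == 0 || ai$n_loops == 0) return(0L)
  arow <- integer(0); dhit <- integer(0)
  for (i in seq_len(n)) {
    ch <- ai$idx[[chrom[i]]]
    if (is.null(ch)) next
    hi <- findInterval(end[i] - 0.5, ch$start)     # anchor start < dom end
    if (hi < 1) next
    lo <- findInterval(start[i] - ch$maxw - 0.5, ch$start)
    if (lo >= hi) next
    cand <- seq.int(lo + 1, hi)
    cand <- cand[ch$end[cand] > start[i]]          # anchor end > dom start
    if (length(cand)) {
      arow <- c(arow, ch$row[cand])
      dhit <- c(dhit, rep.int(i, length(cand)))
    }
  }
  if (!length(arow)) return(0L)
  loop <- ai$loop_id[arow]; side <- ai$side[arow]
  l1 <- loop[side == 1]; d1 <- dhit[side == 1]
  l2 <- loop[side == 2]; d2 <- dhit[side == 2]
  connected <- logical(n)
  for (L in intersect(unique(l1), unique(l2))) {
    s1 <- unique(d1[l1 == L]); s2 <- unique(d2[l2 == L])
    for (d in s1) if (any(s2 != d)) connected[d] <- TRUE
    for (d in s2) if (any(s1 != d)) connected[d] <- TRUE
  }
  sum(connected)
}

count_connected <- function(doms, loops) {
  count_connected_ai(doms$chrom, doms$start, doms$end, anchor_index(loops))
}

#' Permutation test for grand-domain interconnectivity
#'
#' Observed statistic: number of grand domains connected to another grand
#' domain via a loop. Null: each grand domain is relocated uniformly on its
#' own chromosome with its length preserved (shuffled domains may overlap
#' each other); loops stay fixed. p-value is the add-one upper-tail
#' empirical p.
#'
#' @param grand_domains grand-domain interval data frame.
#' @param loops loop data frame.
#' @param chrom_sizes data.frame `chrom, size`.
#' @param n_perm number of permutations (default 1000, >= 100).
#' @param seed RNG seed for the shuffles.
#' @return list: `observed`, `null_counts`, `p`, `n_perm`, `seed`,
#'   `shuffle_mode`.
#' @export
permutation_interaction_test <- function(grand_domains, loops, chrom_sizes,
                                         n_perm = 1000, seed = 1L) {
  if (n_perm < 100) stop("need n_perm >= 100")
  sizes <- stats::setNames(as.numeric(chrom_sizes$size), chrom_sizes$chrom)
  len <- grand_domains$end - grand_domains$start
  sz <- sizes[grand_domains$chrom]
  if (anyNA(sz)) stop("domain chromosome missing from chrom_sizes")
  if (any(len > sz)) stop("domain longer than its chromosome")
  ai <- anchor_index(loops)
  chrom <- grand_domains$chrom
  observed <- count_connected_ai(chrom, grand_domains$start,
                                 grand_domains$end, ai)
  null_counts <- local_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      s <- floor(stats::runif(length(len), 0, sz - len + 1))
      count_connected_ai(chrom, s, s + len, ai)
    }, 0L)
  })
  list(observed = observed, null_counts = null_counts,
       p = empirical_p(observed, null_counts, "greater"),
       n_perm = n_perm, seed = as.integer(seed),
       shuffle_mode = "uniform_same_chrom_length_preserving")
}

#' Loop-target genes of grand domains
#'
#' For every loop anchor overlapping a grand domain, the partner anchor
#' extended by `distance` bp each side is a target region; genes whose body
#' overlaps a target region are targets of that domain. Loops with both
#' anchors in grand domains contribute in both directions; (domain, gene)
#' pairs are deduplicated.
#'
#' @param domains classified domain data frame (grand rows are used).
#' @param loops loop data frame.
#' @param genes gene models.
#' @param distance bp extension of the partner anchor (default 3000).
#' @param marks optional output of [map_domains_to_genes()] for the overlap
#'   report with marked genes.
#' @return list: `targets` (domain_id, gene_id), `target_genes`, and when
#'   `marks` is given `n_overlap_marked`.
#' @export
assign_target_genes <- function(domains, loops, genes, distance = 3000,
                                marks = NULL) {
  grand <- domains[domains$class_label == "grand", , drop = FALSE]
  out <- data.frame(domain_id = character(0), gene_id = character(0))
  if (nrow(grand) && nrow(loops)) {
    a <- anchors_of(loops)
    p <- overlap_pairs(a, grand)
    if (nrow(p)) {
      # partner anchor row: side 1 hit -> side 2 anchor and vice versa
      partner <- ifelse(a$side[p$query] == 1,
                        p$query + nrow(loops), p$query - nrow(loops))
      reg <- data.frame(chrom = a$chrom[partner],
                        start = pmax(0, a$start[partner] - distance),
                        end = a$end[partner] + distance)
      body <- genes[, c("chrom", "start", "end")]
      gp <- overlap_pairs(reg, body)
      if (nrow(gp)) {
        out <- unique(data.frame(
          domain_id = grand$domain_id[p$subject[gp$query]],
          gene_id = genes$gene_id[gp$subject],
          stringsAsFactors = FALSE))
        out <- out[order(out$domain_id, out$gene_id), ]
        rownames(out) <- NULL
      }
    }
  }
  res <- list(targets = out, target_genes = sort(unique(out$gene_id)))
  if (!is.null(marks)) {
    marked <- marks$gene_id[marks$marked & marks$class == "grand"]
    res$n_overlap_marked <- length(intersect(res$target_genes, marked))
  }
  res
}

#' Enrichment-significance correlation between two gene sets
#'
#' Runs upper-tail hypergeometric enrichment of both sets against a term
#' database, keeps terms passing `p < p_cut` and enrichment factor >
#' `ef_cut`, and correlates `-log10 p` across terms enriched in both sets.
#'
#' @param set_a,set_b character vectors of gene ids.
#' @param term_db named list term -> gene ids (see [read_gmt()]).
#' @param universe character vector of all genes.
#' @param p_cut,ef_cut enrichment thresholds (defaults 0.01 and 1.5).
#' @param method correlation method (default `"spearman"`).
#' @return list: `table_a`, `table_b` (per-term records), `shared_terms`,
#'   `r`, `p` (NA with a warning when < 3 shared enriched terms).
#' @export
term_enrichment_correlation <- function(set_a, set_b, term_db, universe,
                                        p_cut = 0.01, ef_cut = 1.5,
                                        method = "spearman") {
  if (!length(term_db)) stop("empty term database")
  set_a <- intersect(set_a, universe); set_b <- intersect(set_b, universe)
  N <- length(universe)
  tab <- function(set) {
    do.call(rbind, lapply(names(term_db), function(tm) {
      members <- intersect(term_db[[tm]], universe)
      e <- hypergeometric_enrichment(length(intersect(set, members)),
                                     length(set), length(members), N,
                                     ef_cut = ef_cut, p_cut = p_cut)
      data.frame(term = tm, k = e$k, n = e$n, K = e$K, N = e$N,
                 p_hyper = e$p_hyper, enrichment_factor = e$enrichment_factor,
                 enriched = e$enriched)
    }))
  }
  ta <- tab(set_a); tb <- tab(set_b)
  shared <- intersect(ta$term[ta$enriched], tb$term[tb$enriched])
  if (length(shared) < 3) {
    warning("fewer than 3 shared enriched terms; correlation skipped")
    return(list(table_a = ta, table_b = tb, shared_terms = shared,
                r = NA_real_, p = NA_real_))
  }
  ia <- match(shared, ta$term); ib <- match(shared, tb$term)
  ct <- rank_correlation(-log10(pmax(ta$p_hyper[ia], 1e-300)),
                         -log10(pmax(tb$p_hyper[ib], 1e-300)), method)
  list(table_a = ta, table_b = tb, shared_terms = shared,
       r = ct$r, p = ct$p)
}
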