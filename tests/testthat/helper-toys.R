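# Shared toy-object builders for classified domains, gene models and loops.

toy_domains <- function(chrom, start, end, class = "typical",
                        control = FALSE) {
  d <- data.frame(chrom = chrom, start = start, end = end)
  d$breadth <- d$end - d$start
  d$signal <- rep(1, nrow(d))
  d$class_label <- rep_len(class, nrow(d))
  d$is_control <- rep_len(control, nrow(d))
  d$domain_id <- sprintf("D%05d", seq_len(nrow(d)))
  d
}

toy_genes <- function(chrom, start, end, strand = "+") {
  strand <- rep_len(strand, length(start))
  make_gene_models(data.frame(
    gene_id = sprintf("g%d", seq_along(start)), chrom = chrom,
    strand = strand,
    tss = ifelse(strand == "-", end, start),
    tes = ifelse(strand == "-", start, end)))
}

toy_loops <- function(c1, s1, e1, c2, s2, e2) {
  data.frame(chrom1 = c1, start1 = s1, end1 = e1,
             chrom2 = c2, start2 = s2, end2 = e2,
             score = rep(NA_real_, length(c1)), inter_chrom = c1 != c2)
}
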