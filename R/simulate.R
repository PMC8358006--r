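#' Configuration of the synthetic epigenome generator
#'
#' The generator emulates a paired normal/tumor epigenome: a heavy-tailed
#' peak-breadth distribution (lognormal body plus Pareto tail), per-domain
#' signal linked to log-breadth, breadth-dependent transcriptional
#' repression of marked genes, TAD-segregated chromatin loops preferring
#' grand-domain anchors, and planted tumor loss/gain of grand domains with
#' an expression and gene-body-methylation response. Default loss/gain/
#' activation/silencing fractions are the published gene-level fractions
#' (66.0%, 18.4%, 37.3%, 19.4%).
#'
#' @param seed master RNG seed.
#' @param n_chroms,chrom_length genome shape (default 4 x 30 Mb).
#' @param n_genes total genes to place (in-domain genes first, remainder as
#'   background genes).
#' @param n_peaks number of H3K27me3 domains planted (each may be emitted
#'   as several sub-peaks separated by < 2 kb gaps).
#' @param breadth_meanlog,breadth_sdlog lognormal body of the breadth law
#'   (defaults log(4500), 0.7: typical domains of 4-5 kb).
#' @param tail_fraction,tail_scale,tail_alpha,tail_cap Pareto upper tail
#'   (default: 6% of domains, scale 50 kb, alpha 1.8, capped at 300 kb).
#' @param signal_a,signal_b,signal_sd log2 signal = a + b * log2(breadth) +
#'   N(0, sd) (RPKM units).
#' @param repression_slope log2-TPM decrease per 100 kb of mark breadth.
#' @param marked_repression constant log2-TPM decrease of any marked gene.
#' @param loss_fraction,gain_fraction fractions of grand domains losing /
#'   gaining H3K27me3 in the tumor.
#' @param activation_fraction_given_loss,silenced_fraction_given_gain
#'   per-gene response probabilities.
#' @param loss_scale,gain_scale multiplicative tumor coverage scaling of
#'   loss/gain domains (defaults 0.2 and 4).
#' @param loop_density total number of loops; `p_in` the fraction forced to
#'   join two grand domains (0 = null mode, loops independent of domains).
#' @param tad_count total TADs tiling the genome.
#' @param tad_span_fraction fraction of grand domains planted to span >= 90%
#'   of their TAD.
#' @param anchor_width loop anchor width in bp.
#' @param methylation_body_shift beta-value increase over the gene body
#'   (not the promoter) of tumor-activated genes.
#' @param missense_shift,dnds_shift constraint shifts of grand-marked genes
#'   (positive missense-Z location shift, multiplicative dN/dS decrease).
#' @param total_mapped simulated library size per ChIP track.
#' @param expr_meanlog2,expr_sdlog2,expr_noise baseline log2 TPM law.
#' @return validated config list.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 4, chrom_length = 3e7,
                              n_genes = 1200, n_peaks = 1000,
                              breadth_meanlog = log(4500), breadth_sdlog = 0.7,
                              tail_fraction = 0.06, tail_scale = 5e4,
                              tail_alpha = 1.8, tail_cap = 3e5,
                              signal_a = -4, signal_b = 0.5, signal_sd = 0.35,
                              repression_slope = 2.5, marked_repression = 1.0,
                              loss_fraction = 0.66, gain_fraction = 0.184,
                              activation_fraction_given_loss = 0.373,
                              silenced_fraction_given_gain = 0.194,
                              loss_scale = 0.2, gain_scale = 4,
                              loop_density = 800, p_in = 0.5,
                              tad_count = 80, tad_span_fraction = 0.3,
                              anchor_width = 8000,
                              methylation_body_shift = 0.15,
                              missense_shift = 1.0, dnds_shift = 0.6,
                              total_mapped = 2e7,
                              expr_meanlog2 = 5, expr_sdlog2 = 1.2,
                              expr_noise = 0.5) {
  cfg <- as.list(environment())
  fr <- c(cfg$tail_fraction, cfg$loss_fraction, cfg$gain_fraction,
          cfg$activation_fraction_given_loss,
          cfg$silenced_fraction_given_gain, cfg$tad_span_fraction, cfg$p_in)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  if (cfg$loss_fraction + cfg$gain_fraction > 1)
    stop("loss_fraction + gain_fraction must be <= 1")
  if (cfg$tail_scale <= 0 || cfg$breadth_sdlog <= 0)
    stop("breadth law must yield positive lengths")
  if (cfg$n_chroms < 1 || cfg$chrom_length < 1e5) stop("genome too small")
  cfg$seed <- as.integer(seed)
  cfg
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483646 + 1)
}

draw_breadths <- function(cfg, n) {
  tail <- stats::runif(n) < cfg$tail_fraction
  b <- stats::rlnorm(n, cfg$breadth_meanlog, cfg$breadth_sdlog)
  if (any(tail)) {
    # Pareto(alpha, xm) by inverse CDF, truncated at tail_cap
    u <- stats::runif(sum(tail))
    b[tail] <- pmin(cfg$tail_cap, cfg$tail_scale * (1 - u)^(-1 / cfg$tail_alpha))
  }
  round(pmax(b, 400))
}

# Planted classification uses the same published rule the caller applies.
planted_classes <- function(breadth, grand_quantile = 0.95,
                            min_breadth = 5e4, narrow_quantile = 0.05) {
  n <- length(breadth)
  cls <- rep("typical", n)
  ord <- order(-breadth)
  cap <- ceiling(round((1 - grand_quantile) * n, 9))
  qcut <- as.numeric(stats::quantile(breadth, grand_quantile))
  g <- ord[breadth[ord] >= qcut & breadth[ord] > min_breadth]
  cls[utils::head(g, cap)] <- "grand"
  ordn <- order(breadth)
  ncut <- as.numeric(stats::quantile(breadth, narrow_quantile))
  nn <- ordn[breadth[ordn] <= ncut]
  cls[utils::head(setdiff(nn, utils::head(g, cap)),
                  ceiling(round(narrow_quantile * n, 9)))] <- "narrow"
  cls
}

#' Simulate the core cohort (in memory)
#'
#' Places domains and genes on the genome, assigns planted classes, tumor
#' states, expression, constraint scores and sub-peak fragmentation.
#' Deterministic given `config$seed`. File emission is layered on top by
#' [simulate_reference()] and [simulate_epigenome_pair()].
#'
#' @param config a [simulation_config()].
#' @return list: `chrom_sizes`, `domains`, `genes`, `peaks`, `expression`,
#'   `constraint`, `de_table`, `config`.
#' @export
simulate_cohort <- function(config) {
  cfg <- config
  local_seed(derive_seed(cfg$seed, 1), {
    chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
    chrom_sizes <- data.frame(chrom = chroms, size = cfg$chrom_length)

    breadth <- draw_breadths(cfg, cfg$n_peaks)
    cls <- planted_classes(breadth)
    n_dom <- cfg$n_peaks

    # genes hosted per domain
    genes_per_dom <- ifelse(cls == "grand", 1 + stats::rpois(n_dom, 2),
                            stats::rbinom(n_dom, 1, 0.5))
    # block layout: domains then leftover background genes, shuffled over
    # chromosomes round-robin
    n_lone <- max(0, cfg$n_genes - sum(genes_per_dom))
    blocks <- data.frame(type = c(rep("domain", n_dom), rep("gene", n_lone)),
                         dom = c(seq_len(n_dom), rep(NA, n_lone)))
    blocks <- blocks[sample.int(nrow(blocks)), ]
    blocks$chrom <- chroms[1 + (seq_len(nrow(blocks)) - 1) %% cfg$n_chroms]

    gene_len <- function(n) round(pmin(3e4, pmax(2000,
      stats::rlnorm(n, log(8000), 0.5))))

    dom_rows <- vector("list", n_dom)
    gene_rows <- list()
    gi <- 0L
    for (ch in chroms) {
      bl <- blocks[blocks$chrom == ch, , drop = FALSE]
      cursor <- 1e4
      for (j in seq_len(nrow(bl))) {
        gap <- 1e4 + stats::rexp(1, 1 / 1e4)
        cursor <- round(cursor + gap)
        if (bl$type[j] == "domain") {
          d <- bl$dom[j]
          s <- cursor; e <- s + breadth[d]
          if (e > cfg$chrom_length - 1e4)
            stop("genome too small to place n_peaks/n_genes; increase ",
                 "chrom_length or n_chroms")
          dom_rows[[d]] <- data.frame(chrom = ch, start = s, end = e)
          k <- genes_per_dom[d]
          if (k > 0) {
            if (cls[d] == "grand") {
              gc <- s + 3000
              for (kk in seq_len(k)) {
                L <- gene_len(1)
                if (gc + L > e - 3000) break
                gi <- gi + 1L
                gene_rows[[gi]] <- data.frame(chrom = ch, start = gc,
                                              end = gc + L, dom = d)
                gc <- gc + L + 5000
              }
            } else {
              L <- gene_len(1)
              gs <- s + floor(stats::runif(1) * max(1, breadth[d] - 500))
              gi <- gi + 1L
              gene_rows[[gi]] <- data.frame(chrom = ch, start = gs,
                                            end = gs + L, dom = d)
              e <- max(e, gs + L)   # advance cursor past the gene
            }
          }
          cursor <- e
        } else {
          L <- gene_len(1)
          if (cursor + L > cfg$chrom_length - 1e4)
            stop("genome too small to place n_peaks/n_genes")
          gi <- gi + 1L
          gene_rows[[gi]] <- data.frame(chrom = ch, start = cursor,
                                        end = cursor + L, dom = NA)
          cursor <- cursor + L
        }
      }
    }
    domains <- do.call(rbind, dom_rows)
    domains$breadth <- domains$end - domains$start
    domains$planted_class <- cls
    domains$signal <- 2^(cfg$signal_a + cfg$signal_b * log2(domains$breadth) +
                           stats::rnorm(n_dom, 0, cfg$signal_sd))
    domains$domain_id <- sprintf("T%05d", seq_len(n_dom))

    # tumor state of grand domains: exact planted counts
    gidx <- which(domains$planted_class == "grand")
    st <- rep("stable", n_dom)
    if (length(gidx)) {
      n_loss <- round(cfg$loss_fraction * length(gidx))
      n_gain <- round(cfg$gain_fraction * length(gidx))
      shuf <- sample(gidx)
      st[shuf[seq_len(n_loss)]] <- "loss"
      if (n_gain > 0) st[shuf[n_loss + seq_len(n_gain)]] <- "gain"
    }
    domains$tumor_state <- st
    domains$tumor_scale <- ifelse(st == "loss", cfg$loss_scale,
                                  ifelse(st == "gain", cfg$gain_scale, 1)) *
      2^stats::rnorm(n_dom, 0, 0.08)

    genes <- do.call(rbind, gene_rows)
    n_g <- nrow(genes)
    genes$gene_id <- sprintf("G%05d", seq_len(n_g))
    genes$strand <- sample(c("+", "-"), n_g, replace = TRUE)
    genes$tss <- ifelse(genes$strand == "-", genes$end, genes$start)
    genes$tes <- ifelse(genes$strand == "-", genes$start, genes$end)
    genes$host_domain <- ifelse(is.na(genes$dom), NA,
                                domains$domain_id[genes$dom])
    genes$host_class <- ifelse(is.na(genes$dom), "none",
                               domains$planted_class[genes$dom])
    genes$host_breadth <- ifelse(is.na(genes$dom), 0, domains$breadth[genes$dom])
    genes$host_state <- ifelse(is.na(genes$dom), "stable",
                               domains$tumor_state[genes$dom])

    # planted per-gene tumor response
    resp <- rep("none", n_g)
    loss_g <- which(genes$host_state == "loss")
    gain_g <- which(genes$host_state == "gain")
    act <- loss_g[stats::runif(length(loss_g)) <
                    cfg$activation_fraction_given_loss]
    sil <- gain_g[stats::runif(length(gain_g)) <
                    cfg$silenced_fraction_given_gain]
    resp[act] <- "activated"; resp[sil] <- "silenced"
    genes$planted_state <- resp

    log2fc_true <- stats::rnorm(n_g, 0, 0.3)
    log2fc_true[act] <- stats::runif(length(act), 1.3, 3)
    log2fc_true[sil] <- -stats::runif(length(sil), 1.3, 3)
    genes$log2fc_true <- log2fc_true

    marked <- !is.na(genes$dom)
    base <- stats::rnorm(n_g, cfg$expr_meanlog2, cfg$expr_sdlog2)
    lt <- base - marked * (cfg$marked_repression +
                             cfg$repression_slope * genes$host_breadth / 1e5) +
      stats::rnorm(n_g, 0, cfg$expr_noise)
    tpm_normal <- 2^lt
    tpm_tumor <- tpm_normal * 2^log2fc_true

    reps <- function(tpm) {
      sapply(1:3, function(r) stats::rnbinom(n_g, size = 8,
                                             mu = tpm * 10 + 0.1))
    }
    cn <- reps(tpm_normal); ct <- reps(tpm_tumor)
    colnames(cn) <- paste0("count_normal_", 1:3)
    colnames(ct) <- paste0("count_tumor_", 1:3)
    expression <- cbind(data.frame(gene_id = genes$gene_id,
                                   tpm_normal = round(tpm_normal, 4),
                                   tpm_tumor = round(tpm_tumor, 4)),
                        cn, ct)

    # synthetic stand-in for a DESeq2-style DE table
    responder <- resp != "none"
    de_table <- data.frame(
      gene_id = genes$gene_id,
      log2fc = round(log2fc_true + stats::rnorm(n_g, 0, 0.15), 4),
      fdr = ifelse(responder, 10^-stats::runif(n_g, 2, 8),
                   stats::runif(n_g, 0.06, 1)))

    gm <- genes$host_class == "grand"
    constraint <- data.frame(
      gene_id = genes$gene_id,
      missense_z = round(stats::rnorm(n_g, 0, 1) + gm * cfg$missense_shift, 4),
      dn_ds = round(stats::rlnorm(n_g, log(0.25), 0.5) *
                      exp(-gm * cfg$dnds_shift), 4))

    # fragment domains into SICER-style sub-peaks with < 2 kb internal gaps
    peaks <- fragment_domains(domains)

    # sort domains genomically and remap the peak -> domain index with them
    ord <- order(domains$chrom, domains$start)
    remap <- integer(n_dom)
    remap[ord] <- seq_len(n_dom)
    domains <- domains[ord, , drop = FALSE]
    rownames(domains) <- NULL
    peaks$dom <- remap[peaks$dom]

    gene_cols <- c("gene_id", "chrom", "strand", "tss", "tes", "start", "end",
                   "host_domain", "host_class", "host_breadth", "host_state",
                   "planted_state", "log2fc_true")
    list(chrom_sizes = chrom_sizes,
         domains = domains,
         genes = genes[order(genes$chrom, genes$start), gene_cols],
         peaks = peaks, expression = expression, constraint = constraint,
         de_table = de_table, config = cfg)
  })
}

fragment_domains <- function(domains) {
  out <- vector("list", nrow(domains))
  for (i in seq_len(nrow(domains))) {
    s <- domains$start[i]; e <- domains$end[i]; b <- e - s
    nf <- if (b < 5000) 1L else if (b < 5e4) sample(2:3, 1) else sample(3:5, 1)
    if (nf == 1) {
      out[[i]] <- data.frame(chrom = domains$chrom[i], start = s, end = e,
                             dom = i)
      next
    }
    cuts <- sort(s + round(stats::runif(nf - 1, 0.1, 0.9) * b))
    cuts <- cuts[c(TRUE, diff(cuts) > 2500)]
    gapw <- round(stats::runif(length(cuts), 300, 1500))
    fs <- c(s, cuts + gapw); fe <- c(cuts, e)
    keep <- fe - fs >= 200
    out[[i]] <- data.frame(chrom = domains$chrom[i], start = fs[keep],
                           end = fe[keep], dom = i)
  }
  sort_intervals(do.call(rbind, out))
}

#' Write the reference annotation files
#'
#' Gene table (TSV dialect), chromosome sizes and the gene constraint table
#' (missense Z shifted up and dN/dS shifted down for grand-marked genes).
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created).
#' @param cohort optional precomputed [simulate_cohort()] result.
#' @return file paths (invisibly), with the cohort in attribute "cohort".
#' @export
simulate_reference <- function(config, out_dir, cohort = NULL) {
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- paste0("seed=", config$seed)
  f <- c(genes = file.path(out_dir, "genes.tsv"),
         chrom_sizes = file.path(out_dir, "chrom_sizes.tsv"),
         constraint = file.path(out_dir, "constraint.tsv"))
  write_tsv(cohort$genes[, c("gene_id", "chrom", "strand", "tss", "tes")],
            f["genes"], prov)
  write_tsv(cohort$chrom_sizes, f["chrom_sizes"], prov)
  write_tsv(cohort$constraint, f["constraint"], prov)
  attr(f, "cohort") <- cohort
  invisible(f)
}

# Depth per RPKM unit given library size: RPKM = depth * 1e9 / total.
depth_per_rpkm <- function(total_mapped) total_mapped / 1e9

build_condition_tracks <- function(cohort) {
  cfg <- cohort$config
  local_seed(derive_seed(cfg$seed, 2), {
    c0 <- depth_per_rpkm(cfg$total_mapped)
    input_rpkm <- 2
    dom <- cohort$domains
    pk <- cohort$peaks
    sig <- dom$signal[pk$dom]
    scale_t <- dom$tumor_scale[pk$dom]
    k27 <- list(
      normal = data.frame(chrom = pk$chrom, start = pk$start, end = pk$end,
                          value = (sig + input_rpkm) * c0),
      tumor = data.frame(chrom = pk$chrom, start = pk$start, end = pk$end,
                         value = (sig * scale_t + input_rpkm) * c0))
    input <- data.frame(chrom = dom$chrom, start = dom$start, end = dom$end,
                        value = input_rpkm * c0)

    g <- cohort$genes
    act <- g$planted_state == "activated"
    marked <- g$host_class != "none"
    lvl_norm <- ifelse(g$host_class == "grand", 0.3, ifelse(marked, 2, 5))
    lvl_tum <- ifelse(act, 9, lvl_norm)
    prom <- data.frame(chrom = g$chrom, start = pmax(0, g$tss - 1000),
                       end = g$tss + 1000)
    body <- data.frame(chrom = g$chrom, start = g$start, end = g$end)
    mk <- function(reg, lvl) {
      r <- data.frame(chrom = reg$chrom, start = reg$start, end = reg$end,
                      value = lvl * c0 * 2^stats::rnorm(nrow(reg), 0, 0.1))
      merge_value_runs(r)
    }
    active <- list(
      h3k4me3 = list(normal = mk(prom, lvl_norm), tumor = mk(prom, lvl_tum)),
      h3k4me1 = list(normal = mk(body, lvl_norm), tumor = mk(body, lvl_tum)),
      h3k27ac = list(normal = mk(body, lvl_norm), tumor = mk(body, lvl_tum)))

    meth <- list(normal = methylation_runs(g, cfg, tumor = FALSE),
                 tumor = methylation_runs(g, cfg, tumor = TRUE))
    list(k27 = k27, input = input, active = active, meth = meth)
  })
}

# Promoter/body runs can touch between close neighbours (grand domains host
# genes 5 kb apart); trim any overlap so tracks stay valid bedGraph.
merge_value_runs <- function(r) {
  r <- sort_intervals(r)
  if (nrow(r) > 1) {
    same <- r$chrom[-1] == r$chrom[-nrow(r)]
    newstart <- pmax(r$start[-1], ifelse(same, r$end[-nrow(r)], -1))
    r$start[-1] <- newstart
    r <- r[r$end > r$start, , drop = FALSE]
  }
  r
}

# 200 bp beta-value runs over gene body +/- 2 kb; promoter bins (TSS +/- 2
# kb) low, body bins high, activated genes shifted up in the body only.
methylation_runs <- function(genes, cfg, tumor) {
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    s <- max(0, genes$start[i] - 2000); e <- genes$end[i] + 2000
    bs <- seq(s, e - 1, by = 200)
    be <- pmin(bs + 200, e)
    mid <- (bs + be) / 2
    promoter <- abs(mid - genes$tss[i]) < 2000
    beta <- ifelse(promoter, 0.15, 0.7)
    if (tumor && genes$planted_state[i] == "activated")
      beta <- beta + ifelse(promoter, 0, cfg$methylation_body_shift)
    beta <- pmin(1, pmax(0, beta + stats::rnorm(length(beta), 0, 0.04)))
    rows[[i]] <- data.frame(chrom = genes$chrom[i], start = bs, end = be,
                            value = round(beta, 4))
  }
  merge_value_runs(do.call(rbind, rows))
}

#' Emit the full paired normal/tumor synthetic dataset
#'
#' Writes peak BEDs, H3K27me3 treatment + input bedGraphs, active-mark
#' bedGraphs (H3K4me3/H3K4me1/H3K27ac), methylation bedGraphs, expression
#' (TPM + negative-binomial replicate counts), a synthetic DE table, the
#' reference files, the planted-truth JSON, and a MANIFEST with checksums.
#'
#' @inheritParams simulate_reference
#' @return named file paths (invisibly); attribute "cohort" carries the
#'   in-memory cohort.
#' @export
simulate_epigenome_pair <- function(config, out_dir) {
  cohort <- simulate_cohort(config)
  if (any(cohort$chrom_sizes$size < max(cohort$domains$end)))
    stop("inconsistent chrom sizes")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- simulate_reference(config, out_dir, cohort = cohort)
  tr <- build_condition_tracks(cohort)
  prov <- paste0("seed=", config$seed)

  path <- function(name) file.path(out_dir, name)
  files <- c(f)
  wl <- function(name, df) {
    p <- path(name)
    writeLines(paste(df$chrom, format_coord(df$start), format_coord(df$end),
                     format(df$value, scientific = FALSE, trim = TRUE),
                     sep = "\t"), p)
    p
  }
  pk <- cohort$peaks
  files["peaks_normal"] <- path("peaks_normal.bed")
  write_bed(pk[, c("chrom", "start", "end")], files["peaks_normal"])
  files["peaks_tumor"] <- path("peaks_tumor.bed")
  write_bed(pk[, c("chrom", "start", "end")], files["peaks_tumor"])
  files["h3k27me3_normal"] <- wl("h3k27me3_normal.bedgraph", tr$k27$normal)
  files["h3k27me3_tumor"] <- wl("h3k27me3_tumor.bedgraph", tr$k27$tumor)
  files["input_normal"] <- wl("input_normal.bedgraph", tr$input)
  files["input_tumor"] <- wl("input_tumor.bedgraph", tr$input)
  for (mk in names(tr$active)) for (cond in c("normal", "tumor")) {
    key <- paste0(mk, "_", cond)
    files[key] <- wl(paste0(key, ".bedgraph"), tr$active[[mk]][[cond]])
  }
  files["methylation_normal"] <- wl("methylation_normal.bedgraph",
                                    tr$meth$normal)
  files["methylation_tumor"] <- wl("methylation_tumor.bedgraph",
                                   tr$meth$tumor)
  files["expression"] <- path("expression.tsv")
  write_tsv(cohort$expression, files["expression"], prov)
  files["de_table"] <- path("de_table.tsv")
  write_tsv(cohort$de_table, files["de_table"],
            c(prov, "synthetic DE table (stand-in for DESeq2 output)"))
  files["truth"] <- path("truth.json")
  write_truth_json(cohort, files["truth"])
  files["manifest"] <- write_manifest(out_dir, files[names(files) != "manifest"])
  attr(files, "cohort") <- cohort
  invisible(files)
}

write_truth_json <- function(cohort, path) {
  cfg <- cohort$config
  truth <- list(
    seed = cfg$seed,
    fractions = list(loss = cfg$loss_fraction, gain = cfg$gain_fraction,
                     activated_given_loss = cfg$activation_fraction_given_loss,
                     silenced_given_gain = cfg$silenced_fraction_given_gain),
    domains = cohort$domains[, c("domain_id", "chrom", "start", "end",
                                 "breadth", "planted_class", "tumor_state")],
    genes = cohort$genes[, c("gene_id", "host_domain", "host_class",
                             "host_state", "planted_state", "log2fc_true")])
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  path
}

#' @rdname simulate_epigenome_pair
#' @param files named file vector previously written into `out_dir`.
#' @export
write_manifest <- function(out_dir, files) {
  p <- file.path(out_dir, "MANIFEST.tsv")
  df <- data.frame(file = basename(unlist(files)),
                   md5 = unname(tools::md5sum(unlist(files))))
  df <- df[order(df$file), ]
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

#' Simulate TADs and chromatin loops
#'
#' TADs tile each chromosome exactly (no gaps or overlap). A
#' `tad_span_fraction` of grand domains get TAD boundaries placed just
#' outside their own edges so they cover >= 90% of that TAD. `p_in` of the
#' loops join two distinct grand domains on one chromosome; the rest are
#' uniform background. With `p_in = 0` (null mode) loop placement is
#' independent of domain positions.
#'
#' @param config a [simulation_config()].
#' @param cohort a [simulate_cohort()] result.
#' @param null_mode override forcing `p_in = 0`.
#' @return list: `tads`, `loops` (both data frames).
#' @export
simulate_interactions <- function(config, cohort, null_mode = FALSE) {
  cfg <- config
  p_in <- if (null_mode) 0 else cfg$p_in
  local_seed(derive_seed(cfg$seed, 3), {
    chroms <- cohort$chrom_sizes$chrom
    L <- cohort$chrom_sizes$size
    per_chrom <- floor(cfg$tad_count / length(chroms))
    if (per_chrom < 1) stop("tad_count below one TAD per chromosome")
    if (per_chrom > min(L) / 5000)
      stop("tad_count exceeding chromosome capacity")
    dom <- cohort$domains
    grand <- dom[dom$planted_class == "grand", , drop = FALSE]
    span_idx <- if (nrow(grand))
      sample(seq_len(nrow(grand)),
             round(cfg$tad_span_fraction * nrow(grand))) else integer(0)
    tad_rows <- lapply(seq_along(chroms), function(ci) {
      ch <- chroms[ci]
      g <- grand[span_idx, , drop = FALSE]
      g <- g[g$chrom == ch, , drop = FALSE]
      cuts <- numeric(0)
      if (nrow(g)) {
        d1 <- floor(stats::runif(nrow(g), 0, 0.05) * g$breadth)
        d2 <- floor(stats::runif(nrow(g), 0, 0.05) * g$breadth)
        cuts <- c(pmax(1, g$start - d1), pmin(L[ci] - 1, g$end + d2))
      }
      extra <- max(0, per_chrom - 1 - length(cuts))
      cuts <- sort(unique(c(0, cuts, floor(stats::runif(extra, 1, L[ci])),
                            L[ci])))
      data.frame(chrom = ch, start = cuts[-length(cuts)], end = cuts[-1])
    })
    tads <- sort_intervals(do.call(rbind, tad_rows))

    n_loops <- cfg$loop_density
    n_in <- round(p_in * n_loops)
    w <- cfg$anchor_width
    anchor_in <- function(d) {
      s <- d$start + floor(stats::runif(nrow(d)) * pmax(1, d$breadth - w))
      data.frame(chrom = d$chrom, start = s, end = pmin(s + w, d$end))
    }
    loops <- NULL
    tab <- table(grand$chrom)
    multi <- names(tab)[tab >= 2]
    if (n_in > 0 && length(multi)) {
      ch_in <- sample(multi, n_in, replace = TRUE)
      pick <- t(vapply(ch_in, function(ch) {
        sample(which(grand$chrom == ch), 2)
      }, integer(2)))
      a1 <- anchor_in(grand[pick[, 1], ]); a2 <- anchor_in(grand[pick[, 2], ])
      loops <- data.frame(chrom1 = a1$chrom, start1 = a1$start, end1 = a1$end,
                          chrom2 = a2$chrom, start2 = a2$start, end2 = a2$end)
    }
    n_bg <- n_loops - if (is.null(loops)) 0 else nrow(loops)
    if (n_bg > 0) {
      ci <- sample(seq_along(chroms), n_bg, replace = TRUE, prob = L / sum(L))
      s1 <- floor(stats::runif(n_bg, 0, L[ci] - w))
      s2 <- floor(stats::runif(n_bg, 0, L[ci] - w))
      bg <- data.frame(chrom1 = chroms[ci], start1 = s1, end1 = s1 + w,
                       chrom2 = chroms[ci], start2 = s2, end2 = s2 + w)
      loops <- rbind(loops, bg)
    }
    loops$score <- NA_real_
    loops$inter_chrom <- loops$chrom1 != loops$chrom2
    rownames(loops) <- NULL
    list(tads = tads, loops = loops)
  })
}
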