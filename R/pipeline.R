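## One-command orchestration: the demo run (simulate -> call -> annotate ->
## TAD -> differential -> report) and a thin subcommand CLI over the same
## stage functions. All analysis tables go through write_tsv (provenance
## headers); logs go to stderr so tables never mix with messages.

#' Read classified domains back from a BED6 file
#'
#' Inverse of [write_domains_bed()]: name is the class label (`control`
#' meaning a control-flagged typical domain), score is signal x 10.
#' @param path BED6 file.
#' @export
read_domains_bed <- function(path) {
  df <- read_bed(path, min_fields = 6)
  df$breadth <- df$end - df$start
  df$signal <- df$score / 10
  df$is_control <- df$name == "control"
  df$class_label <- ifelse(df$is_control, "typical", df$name)
  if (!all(df$class_label %in% c("grand", "typical", "narrow")))
    stop("unexpected domain class label in ", path)
  df$domain_id <- sprintf("D%05d", seq_len(nrow(df)))
  df$n_source_peaks <- NA_integer_
  df
}

log_msg <- function(...) message("[gsdtools] ", ...)

#' Run the full synthetic demo pipeline
#'
#' Simulates a paired normal/tumor epigenome, runs every analysis stage on
#' the emitted files (never on the in-memory truth), writes all result
#' tables plus a markdown report with the figure analogues (breadth
#' histogram, TAD position/connectivity/permutation/multiplexity,
#' loss-gain scatter and integration, activated-gene mark and methylation
#' profiles), and a MANIFEST of checksums. Fully deterministic under
#' `seed`.
#'
#' @param out_dir run directory (created; `sim/` inputs, `results/` tables).
#' @param seed master seed; per-stage seeds are derived from it.
#' @param config optional [simulation_config()] (its seed is overridden).
#' @param params [calling_params()] for domain calling.
#' @param n_perm permutations for the interaction test (default 500; the
#'   published analysis used 1000 — scaled down to keep the demo fast).
#' @return invisible list with every stage result and the file manifest.
#' @export
gsd_demo <- function(out_dir, seed = 7L, config = NULL,
                     params = NULL, n_perm = 500) {
  if (is.null(config)) config <- simulation_config(seed = seed)
  config$seed <- as.integer(seed)
  if (is.null(params)) params <- calling_params(seed = derive_seed(seed, 10))
  sim_dir <- file.path(out_dir, "sim")
  res_dir <- file.path(out_dir, "results")
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)

  log_msg("simulating cohort (seed ", seed, ")")
  files <- simulate_epigenome_pair(config, sim_dir)
  cohort <- attr(files, "cohort")
  ia <- simulate_interactions(config, cohort)
  files["tads"] <- file.path(sim_dir, "tads.bed")
  write_bed(ia$tads, files["tads"])
  files["loops"] <- file.path(sim_dir, "loops.bedpe")
  write_bedpe(ia$loops, files["loops"])
  files["manifest"] <- write_manifest(sim_dir,
                                      files[names(files) != "manifest"])

  res <- run_gsd_stages(
    peaks = files[["peaks_normal"]],
    treatment_normal = files[["h3k27me3_normal"]],
    input_normal = files[["input_normal"]],
    treatment_tumor = files[["h3k27me3_tumor"]],
    input_tumor = files[["input_tumor"]],
    total_mapped = config$total_mapped,
    genes = files[["genes"]], chrom_sizes = files[["chrom_sizes"]],
    expression = files[["expression"]], constraint = files[["constraint"]],
    de_table = files[["de_table"]],
    tads = files[["tads"]], loops = files[["loops"]],
    marks_tracks = lapply(
      stats::setNames(nm = c("h3k4me3", "h3k4me1", "h3k27ac")),
      function(mk) list(normal = files[[paste0(mk, "_normal")]],
                        tumor = files[[paste0(mk, "_tumor")]])),
    methylation = list(normal = files[["methylation_normal"]],
                       tumor = files[["methylation_tumor"]]),
    out_dir = res_dir, params = params, n_perm = n_perm,
    perm_seed = derive_seed(seed, 20))
  res$sim_files <- files
  res$report <- write_demo_report(res, file.path(out_dir, "report.md"),
                                  seed = seed, n_perm = n_perm)
  outs <- list.files(res_dir, full.names = TRUE)
  res$manifest <- write_manifest(out_dir, c(outs, res$report))
  invisible(res)
}

#' Run all analysis stages on files
#'
#' The file-level pipeline behind [gsd_demo()] and the CLI: every input is
#' a path to one of the supported plain-text formats.
#'
#' @param peaks H3K27me3 peak BED (e.g. SICER islands, FDR-filtering is the
#'   caller's business).
#' @param treatment_normal,input_normal,treatment_tumor,input_tumor
#'   bedGraph coverage paths; tumor pair optional (skips differential).
#' @param total_mapped mapped-read count for RPKM scaling.
#' @param genes gene table TSV path; `chrom_sizes` TSV path.
#' @param expression,constraint,de_table optional TSV paths.
#' @param tads,loops optional BED/BEDPE paths (skips the TAD stage when
#'   absent).
#' @param marks_tracks optional nested list of bedGraph paths
#'   `[[mark]][[condition]]`; `methylation` list of beta bedGraph paths.
#' @param out_dir where result tables are written.
#' @param params [calling_params()].
#' @param n_perm,perm_seed permutation-test settings.
#' @return list of stage results (also written as TSVs under `out_dir`).
#' @export
run_gsd_stages <- function(peaks, treatment_normal, input_normal,
                           total_mapped,
                           genes, chrom_sizes,
                           treatment_tumor = NULL, input_tumor = NULL,
                           expression = NULL, constraint = NULL,
                           de_table = NULL, tads = NULL, loops = NULL,
                           marks_tracks = NULL, methylation = NULL,
                           out_dir, params = calling_params(),
                           n_perm = 1000, perm_seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- c(paste0("perm_seed=", perm_seed),
            paste0("merge_gap=", params$merge_gap),
            paste0("grand_quantile=", params$grand_quantile),
            paste0("min_breadth=", params$min_breadth))
  res <- list()

  log_msg("calling domains")
  pk <- read_bed(peaks)
  trk_n <- read_bedgraph(treatment_normal, total_mapped)
  inp_n <- read_bedgraph(input_normal, total_mapped)
  dom <- merge_peaks(pk, params$merge_gap)
  dom$signal <- quantify_domain_signal(dom, trk_n, inp_n)
  classified <- suppressWarnings(classify_domains(dom, params))
  res$domains <- classified
  res$thresholds <- attr(classified, "thresholds")
  write_domains_bed(classified, file.path(out_dir, "domains.bed"))
  write_tsv(res$thresholds, file.path(out_dir, "thresholds.tsv"), prov)
  mg <- metagene_matrix(classified[classified$class_label == "grand", ],
                        trk_n)
  res$metagene_grand <- attr(mg, "mean_profile")
  mgt <- metagene_matrix(classified[classified$class_label == "typical", ],
                         trk_n)
  res$metagene_typical <- attr(mgt, "mean_profile")
  write_tsv(data.frame(bin = seq_along(res$metagene_grand),
                       grand = res$metagene_grand,
                       typical = res$metagene_typical),
            file.path(out_dir, "metagene.tsv"), prov)

  gm <- read_gene_table(genes)
  res$marks <- map_domains_to_genes(classified, gm)
  write_tsv(res$marks, file.path(out_dir, "gene_marks.tsv"), prov)
  if (!is.null(constraint)) {
    log_msg("constraint association")
    res$constraint <- constraint_association(res$marks, read_tsv(constraint))
    write_tsv(res$constraint$bin_summary,
              file.path(out_dir, "constraint_bins.tsv"), prov)
  }
  expr_tab <- NULL
  if (!is.null(expression)) {
    expr_tab <- read_tsv(expression)
    e <- data.frame(gene_id = expr_tab$gene_id, tpm = expr_tab$tpm_normal)
    res$expression_trend <- breadth_expression_trend(res$marks, e)
    write_tsv(res$expression_trend$bin_table,
              file.path(out_dir, "breadth_expression.tsv"),
              c(prov, paste0("spearman_r=", round(res$expression_trend$r, 4))))
  }

  if (!is.null(tads) && !is.null(loops)) {
    log_msg("TAD / loop integration (n_perm = ", n_perm, ")")
    td <- read_bed(tads)
    lp <- read_bedpe(loops)
    cs <- read_tsv(chrom_sizes)
    res$tad_census <- tad_overlap_summary(classified, td, lp)
    write_tsv(res$tad_census$census, file.path(out_dir, "tad_census.tsv"),
              prov)
    res$tad_positions <- tad_position_profile(classified, td)
    write_tsv(res$tad_positions$profile,
              file.path(out_dir, "tad_position_profile.tsv"), prov)
    res$connectivity <- interaction_connectivity(classified, lp)
    mt <- do.call(rbind, lapply(names(res$connectivity), function(cl) {
      cc <- res$connectivity[[cl]]
      data.frame(class = cl, n = cc$n,
                 connected_fraction = cc$connected_fraction,
                 mult_1 = cc$multiplexity[["1"]],
                 mult_2 = cc$multiplexity[["2"]],
                 mult_3plus = cc$multiplexity[[">=3"]])
    }))
    write_tsv(mt, file.path(out_dir, "connectivity.tsv"), prov)
    res$permutation <- permutation_interaction_test(
      classified[classified$class_label == "grand", ], lp, cs,
      n_perm = n_perm, seed = perm_seed)
    write_tsv(data.frame(observed = res$permutation$observed,
                         p = res$permutation$p, n_perm = n_perm,
                         seed = perm_seed),
              file.path(out_dir, "permutation.tsv"), prov)
    write_tsv(data.frame(null_count = res$permutation$null_counts),
              file.path(out_dir, "permutation_null.tsv"), prov)
    res$targets <- assign_target_genes(classified, lp, gm, marks = res$marks)
    write_tsv(res$targets$targets, file.path(out_dir, "target_genes.tsv"),
              prov)
  }

  if (!is.null(treatment_tumor) && !is.null(input_tumor)) {
    log_msg("differential loss/gain integration")
    trk_t <- read_bedgraph(treatment_tumor, total_mapped)
    inp_t <- read_bedgraph(input_tumor, total_mapped)
    sn <- gene_k27_signal(gm, trk_n, inp_n)
    st <- gene_k27_signal(gm, trk_t, inp_t)
    k27 <- classify_h3k27me3_change(sn, st)
    de <- if (!is.null(de_table)) {
      d <- read_tsv(de_table)
      names(d)[names(d) == "log2FC"] <- "log2fc"
      names(d)[names(d) == "FDR"] <- "fdr"
      d
    } else NULL
    calls <- integrate_expression_changes(k27, de_table = de)
    calls <- merge(calls, res$marks[, c("gene_id", "class", "is_control",
                                        "mark_breadth")], by = "gene_id")
    res$calls <- calls
    write_tsv(calls, file.path(out_dir, "differential_calls.tsv"), prov)
    bg <- calls$expr_log2fc[!is.na(calls$expr_log2fc)]
    res$summary <- list(
      grand = activation_summary(calls[calls$class == "grand", ], bg),
      narrow = activation_summary(calls[calls$class == "narrow", ], bg),
      control = activation_summary(calls[calls$is_control, ], bg))
    st_tab <- do.call(rbind, lapply(names(res$summary), function(cl) {
      p <- res$summary[[cl]]$percentages
      data.frame(class = cl, n = p$n_total, n_loss = p$n_loss,
                 n_gain = p$n_gain, n_activated = p$n_activated,
                 n_silenced = p$n_silenced, loss_pct = p$loss_pct,
                 gain_pct = p$gain_pct,
                 activated_of_loss_pct = p$activated_of_loss_pct,
                 silenced_of_gain_pct = p$silenced_of_gain_pct,
                 spearman_r = if (is.null(res$summary[[cl]]$correlation))
                   NA else res$summary[[cl]]$correlation$r)
    }))
    write_tsv(st_tab, file.path(out_dir, "activation_summary.tsv"), prov)
    cum <- res$summary$grand$cumulative
    if (!is.null(cum))
      write_tsv(cum, file.path(out_dir, "cumulative_expression.tsv"), prov)

    if (!is.null(marks_tracks)) {
      log_msg("activated-gene mark/methylation profiles")
      act_ids <- calls$gene_id[calls$class == "grand" &
                                 calls$activation_class == "activated"]
      if (length(act_ids) >= 3) {
        tr <- lapply(marks_tracks, function(mc)
          lapply(mc, read_bedgraph, total_mapped = total_mapped))
        me <- if (!is.null(methylation))
          lapply(methylation, read_bedgraph, value_bounds = c(0, 1))
        res$profiles <- region_mark_profiles(
          gm[gm$gene_id %in% act_ids, ], tr, methylation = me)
        ptab <- do.call(rbind, lapply(names(res$profiles$profiles),
                                      function(mk) {
          p <- res$profiles$profiles[[mk]]
          if (is.null(p)) return(NULL)
          data.frame(mark = mk, bin = seq_along(p$normal),
                     normal = p$normal, tumor = p$tumor)
        }))
        write_tsv(ptab, file.path(out_dir, "activated_profiles.tsv"), prov)
        if (!is.null(res$profiles$methylation))
          write_tsv(data.frame(
            delta_promoter = res$profiles$methylation$mean_delta_promoter,
            delta_body = res$profiles$methylation$mean_delta_body,
            body_hyper_no_promoter_hypo =
              res$profiles$methylation$body_hyper_no_promoter_hypo),
            file.path(out_dir, "methylation_delta.tsv"), prov)
      } else {
        log_msg("fewer than 3 activated genes; profile stage skipped")
      }
    }
  }
  res
}

write_demo_report <- function(res, path, seed, n_perm) {
  th <- res$thresholds
  fmt <- function(x, d = 3) format(round(x, d), nsmall = 0, trim = TRUE)
  b <- res$domains$breadth
  hist_tab <- table(cut(b / 1000, breaks = c(0, 2, 5, 10, 25, 50, 100, Inf)))
  lines <- c(
    "# Grand H3K27me3 silencer domain demo run",
    "",
    paste0("Seed: ", seed, "; domains called: ", th$n,
           " (grand ", th$n_grand, ", narrow ", th$n_narrow,
           ", control ", th$n_control, ")"),
    paste0("Grand breadth cut-off: ", fmt(th$grand_breadth_cut / 1000, 1),
           " kb (floor ", th$min_breadth / 1000, " kb)"),
    "",
    "## Breadth distribution (kb, counts)",
    paste0("- ", names(hist_tab), ": ", as.integer(hist_tab)),
    "",
    "## Gene association",
    paste0("- marked genes: ", sum(res$marks$marked),
           " (grand-marked: ", sum(res$marks$class == "grand"), ")"))
  if (!is.null(res$constraint)) {
    tz <- res$constraint$tests
    lines <- c(lines,
      paste0("- missense Z grand vs other marked: p = ",
             signif(tz$missense_z$p_value, 3), " (", tz$missense_z$direction, ")"),
      paste0("- dN/dS grand vs other marked: p = ",
             signif(tz$dn_ds$p_value, 3), " (", tz$dn_ds$direction, ")"))
  }
  if (!is.null(res$expression_trend))
    lines <- c(lines,
      paste0("- breadth-expression Spearman r = ",
             fmt(res$expression_trend$r), ", p = ",
             signif(res$expression_trend$p, 3)))
  if (!is.null(res$tad_census)) {
    cg <- res$tad_census$census
    g <- cg[cg$class == "grand", ]
    lines <- c(lines, "", "## TAD / loop integration",
      paste0("- grand domains overlapping TADs: ", g$n_overlap_tad, "/", g$n,
             "; marking anchors: ", g$n_marks_anchor,
             "; spanning a TAD: ", g$n_spans_tad,
             " (", fmt(100 * g$frac_spans_tad, 1), "%)"),
      paste0("- connectivity (grand/narrow/control): ",
             paste(vapply(res$connectivity, function(x)
               fmt(x$connected_fraction, 2), ""), collapse = " / ")),
      paste0("- permutation test: observed ", res$permutation$observed,
             " connected grand domains, p = ",
             signif(res$permutation$p, 3), " (", n_perm, " shuffles)"),
      paste0("- loop-target genes: ", length(res$targets$target_genes),
             " (overlap with grand-marked: ", res$targets$n_overlap_marked,
             ")"))
  }
  if (!is.null(res$summary)) {
    p <- res$summary$grand$percentages
    lines <- c(lines, "", "## Tumor loss/gain of grand domains",
      paste0("- grand-marked genes: ", p$n_total, "; loss ", p$n_loss,
             " (", p$loss_pct, "%), gain ", p$n_gain, " (", p$gain_pct, "%)"),
      paste0("- activated (loss + up): ", p$n_activated, " of ", p$n_loss,
             " (", p$activated_of_loss_pct, "%); silenced (gain + down): ",
             p$n_silenced, " of ", p$n_gain, " (", p$silenced_of_gain_pct,
             "%)"),
      paste0("- Spearman(delta K27, delta expr), grand: ",
             fmt(res$summary$grand$correlation$r)))
  }
  if (!is.null(res$profiles) && !is.null(res$profiles$methylation)) {
    m <- res$profiles$methylation
    lines <- c(lines,
      paste0("- methylation delta (activated genes): body ",
             fmt(m$mean_delta_body), ", promoter ",
             fmt(m$mean_delta_promoter), " (body hypermethylation without ",
             "promoter hypomethylation: ", m$body_hyper_no_promoter_hypo,
             ")"))
  }
  writeLines(lines, path)
  path
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `call-domains`, `annotate-genes`, `tad`,
#' `differential`, `demo`, `report`. Flags are `--key value` pairs
#' mirroring the stage parameters (`--merge-gap`, `--grand-quantile`,
#' `--min-breadth`, `--n-perm`, `--target-distance`,
#' `--entirety-threshold`, `--fold-threshold`, `--seed`, `--out`, ...).
#'
#' @param args character vector (default `commandArgs(trailingOnly=TRUE)`).
#' @return 0 on success (invisibly); errors propagate (the installed
#'   `inst/cli/gsd` wrapper converts them to a non-zero exit status).
#' @export
gsd_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1)
    stop("usage: gsd <simulate|call-domains|annotate-genes|tad|",
         "differential|demo|report> [--flag value ...]")
  cmd <- args[1]
  fl <- parse_flags(args[-1])
  need <- function(key, what) {
    v <- fl[[key]]
    if (is.null(v)) stop("missing required --", key, " (", what, ")")
    v
  }
  need_file <- function(key, what) {
    v <- need(key, what)
    if (!file.exists(v)) stop("input not found: ", v, " (", what, ")")
    v
  }
  num <- function(key, default) {
    if (is.null(fl[[key]])) default else as.numeric(fl[[key]])
  }
  out <- need("out", "output directory")
  seed <- as.integer(num("seed", 7))
  params <- calling_params(
    merge_gap = num("merge-gap", 2000),
    grand_quantile = num("grand-quantile", 0.95),
    min_breadth = num("min-breadth", 50000),
    narrow_quantile = num("narrow-quantile", 0.05),
    control_fraction = num("control-fraction", 0.05),
    seed = seed)
  if (cmd == "demo") {
    gsd_demo(out, seed = seed, params = params,
             n_perm = num("n-perm", 500))
  } else if (cmd == "simulate") {
    cfg <- simulation_config(seed = seed)
    files <- simulate_epigenome_pair(cfg, out)
    ia <- simulate_interactions(cfg, attr(files, "cohort"))
    write_bed(ia$tads, file.path(out, "tads.bed"))
    write_bedpe(ia$loops, file.path(out, "loops.bedpe"))
    write_manifest(out, c(files[names(files) != "manifest"],
                          file.path(out, "tads.bed"),
                          file.path(out, "loops.bedpe")))
  } else if (cmd == "call-domains") {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    pk <- read_bed(need_file("peaks", "peak BED"))
    tm <- num("total-mapped", NA)
    if (!is.finite(tm)) stop("missing required --total-mapped")
    trk <- read_bedgraph(need_file("treatment", "treatment bedGraph"), tm)
    inp <- read_bedgraph(need_file("input", "input bedGraph"), tm)
    dom <- merge_peaks(pk, params$merge_gap)
    dom$signal <- quantify_domain_signal(dom, trk, inp)
    cd <- suppressWarnings(classify_domains(dom, params))
    write_domains_bed(cd, file.path(out, "domains.bed"))
    write_tsv(attr(cd, "thresholds"), file.path(out, "thresholds.tsv"))
  } else if (cmd == "annotate-genes") {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    cd <- read_domains_bed(need_file("domains", "domains BED"))
    gm <- read_gene_table(need_file("genes", "gene table TSV"))
    marks <- map_domains_to_genes(cd, gm,
                                  extension = num("mark-extension", 2000))
    write_tsv(marks, file.path(out, "gene_marks.tsv"))
  } else if (cmd == "tad") {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    cd <- read_domains_bed(need_file("domains", "domains BED"))
    td <- read_bed(need_file("tads", "TAD BED"))
    lp <- read_bedpe(need_file("loops", "loop BEDPE"))
    cs <- read_tsv(need_file("chrom-sizes", "chromosome sizes TSV"))
    cen <- tad_overlap_summary(cd, td, lp,
                               coverage_threshold = num("entirety-threshold",
                                                        0.9))
    write_tsv(cen$census, file.path(out, "tad_census.tsv"))
    pt <- permutation_interaction_test(
      cd[cd$class_label == "grand", ], lp, cs,
      n_perm = num("n-perm", 1000), seed = seed)
    write_tsv(data.frame(observed = pt$observed, p = pt$p,
                         n_perm = pt$n_perm, seed = pt$seed),
              file.path(out, "permutation.tsv"))
  } else if (cmd == "differential") {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    gm <- read_gene_table(need_file("genes", "gene table TSV"))
    tm <- num("total-mapped", NA)
    if (!is.finite(tm)) stop("missing required --total-mapped")
    sn <- gene_k27_signal(gm,
      read_bedgraph(need_file("treatment-normal", "bedGraph"), tm),
      read_bedgraph(need_file("input-normal", "bedGraph"), tm))
    st <- gene_k27_signal(gm,
      read_bedgraph(need_file("treatment-tumor", "bedGraph"), tm),
      read_bedgraph(need_file("input-tumor", "bedGraph"), tm))
    k27 <- classify_h3k27me3_change(sn, st,
      fold_threshold = num("fold-threshold", 1.0))
    de <- read_tsv(need_file("de-table", "differential expression TSV"))
    calls <- integrate_expression_changes(k27, de_table = de)
    write_tsv(calls, file.path(out, "differential_calls.tsv"))
  } else if (cmd == "report") {
    run <- need("run", "demo run directory")
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    if (!file.exists(file.path(run, "report.md")))
      stop("no report.md in ", run, "; run the demo first")
    file.copy(file.path(run, "report.md"), file.path(out, "report.md"),
              overwrite = TRUE)
  } else {
    stop("unknown subcommand: ", cmd)
  }
  invisible(0L)
}

parse_flags <- function(args) {
  fl <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("unexpected argument: ", args[i])
    key <- substring(args[i], 3)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      fl[[key]] <- TRUE; i <- i + 1
    } else {
      fl[[key]] <- args[i + 1]; i <- i + 2
    }
  }
  fl
}
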