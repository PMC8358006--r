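# scaled-down config so the suite stays fast; the acceptance tests run the
# full demo-scale world
small_cfg <- function(seed = 1, ...) {
  simulation_config(seed = seed, n_chroms = 2, chrom_length = 1.2e7,
                    n_peaks = 300, n_genes = 350, loop_density = 400,
                    tad_count = 24, ...)
}

test_that("same seed gives byte-identical outputs, different seed differs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  simulate_epigenome_pair(small_cfg(5), d1)
  simulate_epigenome_pair(small_cfg(5), d2)
  simulate_epigenome_pair(small_cfg(6), d3)
  m1 <- readLines(file.path(d1, "MANIFEST.tsv"))
  expect_identical(m1, readLines(file.path(d2, "MANIFEST.tsv")))
  expect_false(identical(m1, readLines(file.path(d3, "MANIFEST.tsv"))))
  # the generator does not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); simulate_cohort(small_cfg(2)); b <- runif(1)
  expect_identical(a, b)
})

test_that("emitted files round-trip through the readers", {
  d <- withr::local_tempdir()
  cfg <- small_cfg(11)
  files <- simulate_epigenome_pair(cfg, d)
  pk <- read_bed(files[["peaks_normal"]])
  expect_gt(nrow(pk), cfg$n_peaks)   # domains are fragmented into sub-peaks
  tr <- read_bedgraph(files[["h3k27me3_normal"]], cfg$total_mapped)
  expect_s3_class(tr, "coverage_track")
  me <- read_bedgraph(files[["methylation_tumor"]], value_bounds = c(0, 1))
  expect_true(all(track_runs(me)$value >= 0 & track_runs(me)$value <= 1))
  g <- read_gene_table(files[["genes"]])
  expect_equal(nrow(g), nrow(attr(files, "cohort")$genes))
  expect_true(all(c("log2fc", "fdr") %in%
                    names(read_tsv(files[["de_table"]]))))
  truth <- jsonlite::read_json(files[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$seed, 11)
  man <- utils::read.table(files[["manifest"]], header = TRUE, sep = "\t")
  expect_true(all(c("genes.tsv", "truth.json") %in% man$file))
})

test_that("planted tumor states scale coverage as configured", {
  d <- withr::local_tempdir()
  cfg <- small_cfg(21)
  files <- simulate_epigenome_pair(cfg, d)
  co <- attr(files, "cohort")
  tn <- read_bedgraph(files[["h3k27me3_normal"]], cfg$total_mapped)
  tt <- read_bedgraph(files[["h3k27me3_tumor"]], cfg$total_mapped)
  dd <- co$domains
  sn <- track_region_sum(tn, dd$chrom, dd$start, dd$end)
  st <- track_region_sum(tt, dd$chrom, dd$start, dd$end)
  ratio <- st / sn
  # recomputed from the emitted bedGraphs, not from the truth object
  expect_lt(mean(ratio[dd$tumor_state == "loss"]), 0.5)
  expect_gt(mean(ratio[dd$tumor_state == "gain"]), 2)
  expect_equal(mean(ratio[dd$tumor_state == "stable"]), 1, tolerance = 0.1)
})

test_that("truth fractions match config within binomial tolerance", {
  co <- simulate_cohort(small_cfg(31))
  cfg <- co$config
  g <- co$domains[co$domains$planted_class == "grand", ]
  # domain-level loss/gain are planted as exact counts
  expect_equal(sum(g$tumor_state == "loss"),
               round(cfg$loss_fraction * nrow(g)))
  expect_equal(sum(g$tumor_state == "gain"),
               round(cfg$gain_fraction * nrow(g)))
  loss_genes <- co$genes$host_state == "loss"
  p_hat <- mean(co$genes$planted_state[loss_genes] == "activated")
  se <- sqrt(cfg$activation_fraction_given_loss *
               (1 - cfg$activation_fraction_given_loss) / sum(loss_genes))
  expect_lt(abs(p_hat - cfg$activation_fraction_given_loss), 3 * se)
})

test_that("breadth law: no tail means no grand domains", {
  co <- simulate_cohort(small_cfg(41, tail_fraction = 0))
  expect_equal(sum(co$domains$planted_class == "grand"), 0)
  dom <- merge_peaks(co$peaks, 2000)
  dom$signal <- 0
  cd <- classify_domains(dom, calling_params(seed = 1))
  expect_equal(sum(cd$class_label == "grand"), 0)
})

test_that("degenerate sizes work or fail loudly", {
  tiny <- simulation_config(seed = 3, n_chroms = 1, chrom_length = 2e6,
                            n_peaks = 8, n_genes = 1, loop_density = 10,
                            tad_count = 4)
  d <- withr::local_tempdir()
  files <- simulate_reference(tiny, d)
  expect_gte(nrow(read_gene_table(files[["genes"]])), 1)
  # genome too small to hold the requested content
  over <- simulation_config(seed = 3, n_chroms = 1, chrom_length = 2e5,
                            n_peaks = 300, n_genes = 300)
  expect_error(simulate_cohort(over), "genome too small")
})

test_that("TADs tile chromosomes and loops respect p_in extremes", {
  cfg <- small_cfg(51, p_in = 1)
  co <- simulate_cohort(cfg)
  ia <- simulate_interactions(cfg, co)
  for (ch in unique(ia$tads$chrom)) {
    t <- ia$tads[ia$tads$chrom == ch, ]
    expect_equal(t$start[1], 0)
    expect_equal(t$end[nrow(t)], cfg$chrom_length)
    expect_equal(t$start[-1], t$end[-nrow(t)])   # no gaps, no overlap
  }
  dom <- co$domains
  dom$class_label <- dom$planted_class
  dom$is_control <- FALSE
  cc <- interaction_connectivity(dom, ia$loops,
                                 classes = c("grand", "narrow"))
  expect_gte(cc$grand$connected_fraction, 0.9)  # all loops forced grand-grand
  expect_lte(cc$narrow$connected_fraction, 0.1)

  # a spanning fraction of grand domains covers >= 90% of a TAD
  ts <- tad_overlap_summary(dom, ia$tads, ia$loops)
  expect_gte(ts$census$frac_spans_tad[ts$census$class == "grand"],
             cfg$tad_span_fraction * 0.5)
  expect_error(simulate_interactions(small_cfg(1, tad_count = 1), co),
               "tad_count")
})
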