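test_that("tad_overlap_summary flags overlap, anchors and spanning", {
  dom <- toy_domains("chr1", c(0, 500000), c(100000, 500010), "grand")
  tads <- data.frame(chrom = "chr1", start = c(10000, 90000),
                     end = c(90000, 200000))
  loops <- toy_loops("chr1", 1000, 2000, "chr1", 300000, 301000)
  ts <- tad_overlap_summary(dom, tads, loops)
  r <- ts$relations
  # domain [0,100k) covers TAD [10k,90k) fully -> fraction 1, spans
  expect_equal(r$covered_fraction_of_tad[1], 1.0)
  expect_true(r$spans_entire_tad[1])
  expect_true(r$marks_anchor[1])
  # far domain: nothing set
  expect_false(r$overlaps_tad[2] || r$marks_anchor[2])

  # strict >= at the coverage threshold
  dom89 <- toy_domains("chr1", 10000, 10000 + 0.89 * 80000)
  expect_false(tad_overlap_summary(dom89, tads,
                                   loops)$relations$spans_entire_tad)
  dom90 <- toy_domains("chr1", 10000, 10000 + 0.90 * 80000)
  expect_true(tad_overlap_summary(dom90, tads,
                                  loops)$relations$spans_entire_tad)

  expect_error(tad_overlap_summary(dom, data.frame(chrom = "chr1",
                                                   start = c(0, 5000),
                                                   end = c(10000, 20000)),
                                   loops), "overlapping TADs")
})

test_that("tad_position_profile normalizes positions to [-1, 1]", {
  tads <- data.frame(chrom = "chr1", start = 0, end = 100000)
  center <- toy_domains("chr1", 45000, 55000)
  expect_equal(tad_position_profile(center, tads)$positions$position, 0)
  atstart <- toy_domains("chr1", 0, 2)
  expect_equal(tad_position_profile(atstart, tads)$positions$position,
               -0.99998)
  outside <- toy_domains("chr2", 0, 10)
  expect_equal(tad_position_profile(outside, tads)$n_excluded, 1)

  # symmetric random placement gives a symmetric profile
  set.seed(3)
  s <- sample.int(99000, 400, replace = TRUE)
  dd <- toy_domains("chr1", s, s + 1000)
  pr <- tad_position_profile(dd, tads, n_bins = 10)$positions$position
  expect_lt(abs(mean(pr)), 0.1)
})

test_that("connectivity matches the brute-force oracle and excludes self-loops", {
  # two domains joined by one loop
  dom <- toy_domains("chr1", c(0, 50000), c(10000, 60000), "grand")
  lp <- toy_loops("chr1", 1000, 2000, "chr1", 51000, 52000)
  cc <- interaction_connectivity(dom, lp, classes = "grand")$grand
  expect_equal(cc$connected_fraction, 1)
  expect_equal(unname(cc$multiplexity), c(2L, 0L, 0L))

  # both anchors inside one domain: self-loop, not connected
  self_lp <- toy_loops("chr1", 1000, 2000, "chr1", 5000, 6000)
  cc2 <- interaction_connectivity(dom, self_lp, classes = "grand")$grand
  expect_equal(cc2$connected_fraction, 0)

  set.seed(55)
  for (i in 1:100) {
    nd <- sample(2:8, 1); nl <- sample(1:10, 1)
    d <- random_peaks(nd, span = 5000)
    d <- toy_domains(d$chrom, d$start, d$end, "grand")
    a1 <- random_peaks(nl, span = 5000); a2 <- random_peaks(nl, span = 5000)
    lp <- toy_loops(a1$chrom, a1$start, a1$end, a2$chrom, a2$start, a2$end)
    got <- interaction_connectivity(d, lp, classes = "grand")$grand
    expect_equal(got$per_domain$connected, oracle_connectivity(d, lp),
                 info = paste("case", i))
  }
})

test_that("permutation test is deterministic, calibrated at the extremes", {
  dom <- toy_domains("chr1", c(0, 50000), c(10000, 60000), "grand")
  cs <- data.frame(chrom = "chr1", size = 1e7)

  # no loops: observed 0, p = 1
  r0 <- permutation_interaction_test(dom, toy_loops(character(0), numeric(0),
                                                    numeric(0), character(0),
                                                    numeric(0), numeric(0)),
                                     cs, n_perm = 100, seed = 1)
  expect_equal(r0$observed, 0L)
  expect_equal(r0$p, 1)

  # loops exactly on the true domains in a sparse genome: p at the floor
  lp <- toy_loops("chr1", 1000, 2000, "chr1", 51000, 52000)
  r1 <- permutation_interaction_test(dom, lp, cs, n_perm = 199, seed = 5)
  expect_equal(r1$observed, 2L)
  expect_equal(r1$p, 1 / 200)

  r2 <- permutation_interaction_test(dom, lp, cs, n_perm = 199, seed = 5)
  expect_identical(r1$null_counts, r2$null_counts)
  expect_error(permutation_interaction_test(
    toy_domains("chr1", 0, 2e7, "grand"), lp, cs, n_perm = 100),
    "longer than its chromosome")
})

test_that("assign_target_genes respects the <= 3 kb rule and deduplicates", {
  dom <- toy_domains("chr1", 0, 50000, "grand")
  # partner anchor [99000,100000) extended +/- 3 kb -> region [96000,103000)
  g <- toy_genes("chr1", c(102000, 103001), c(104000, 107000))
  lp <- toy_loops("chr1", 1000, 2000, "chr1", 99000, 100000)
  tg <- assign_target_genes(dom, lp, g)
  # gene1 2 kb from the anchor -> targeted; gene2 3001 bp away -> not
  expect_equal(tg$target_genes, "g1")

  # boundary: half-open extension, a gene starting exactly at end + 3000
  # has zero overlap with the target region
  g3 <- toy_genes("chr1", 103000, 104000)
  expect_equal(length(assign_target_genes(dom, lp, g3)$target_genes), 0)
  g4 <- toy_genes("chr1", 102999, 104000)
  expect_equal(assign_target_genes(dom, lp, g4)$target_genes, "g1")

  # loop with both anchors in grand domains: both directions, deduplicated
  dom2 <- toy_domains("chr1", c(0, 200000), c(50000, 260000), "grand")
  gg <- toy_genes("chr1", c(10000, 210000), c(12000, 212000))
  both <- toy_loops("chr1", 9000, 13000, "chr1", 209000, 213000)
  tg2 <- assign_target_genes(dom2, both, gg,
                             marks = map_domains_to_genes(dom2, gg))
  expect_equal(nrow(tg2$targets), 2)
  expect_equal(sort(tg2$target_genes), c("g1", "g2"))
  expect_equal(tg2$n_overlap_marked, 2)
})

test_that("term_enrichment_correlation behaves at the identity and threshold", {
  universe <- sprintf("g%03d", 1:200)
  term_db <- list(A = universe[1:20], B = universe[21:40],
                  C = universe[41:60], D = universe[1:100])
  set_a <- universe[c(1:15, 25:35, 45:55)]
  r_id <- term_enrichment_correlation(set_a, set_a, term_db, universe)
  expect_equal(r_id$r, 1)
  expect_setequal(r_id$shared_terms, c("A", "B", "C", "D"))

  # disjoint random set: no shared enriched terms -> warning, NA r
  set_b <- universe[150:190]
  expect_warning(r_nd <- term_enrichment_correlation(set_a, set_b, term_db,
                                                     universe),
                 "fewer than 3 shared")
  expect_true(is.na(r_nd$r))
})
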