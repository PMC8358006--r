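test_that("merge_peaks handles the documented gap cases", {
  one <- merge_peaks(data.frame(chrom = "chr1", start = 0, end = 1000), 2000)
  expect_equal(one$n_source_peaks, 1)
  expect_equal(one$breadth, 1000)

  two <- merge_peaks(data.frame(chrom = "chr1", start = c(0, 2500),
                                end = c(1000, 3000)), 2000)
  expect_equal(nrow(two), 1)           # gap 1500 <= 2000 -> merged
  expect_equal(two$end, 3000)
  expect_equal(two$n_source_peaks, 2)

  sep <- merge_peaks(data.frame(chrom = "chr1", start = c(0, 3001),
                                end = c(1000, 4000)), 2000)
  expect_equal(nrow(sep), 2)           # gap 2001 > 2000 -> kept apart

  # same coordinates on different chromosomes never merge
  cc <- merge_peaks(data.frame(chrom = c("chr1", "chr2"), start = 0,
                               end = 1000), 5000)
  expect_equal(nrow(cc), 2)
})

test_that("merge_peaks equals the per-base union oracle on random toys", {
  set.seed(42)
  for (i in 1:100) {
    pk <- random_peaks(sample(2:12, 1))
    gap <- sample(c(0, 5, 50, 300), 1)
    got <- merge_peaks(pk, gap)
    want <- oracle_merge(pk, gap)
    expect_equal(got[, c("chrom", "start", "end")], want, info = paste(i))
  }
})

test_that("quantify_domain_signal implements input-subtracted RPKM", {
  # 1000 reads over 10 kb at 10 M mapped -> RPKM 10; input 500 -> signal 5
  treat <- toy_track(chrom = "c", start = 0, end = 10000, value = 0.1,
                     total_mapped = 1e7)
  inp <- toy_track(chrom = "c", start = 0, end = 10000, value = 0.05,
                   total_mapped = 1e7)
  reg <- data.frame(chrom = "c", start = 0, end = 10000)
  expect_equal(quantify_domain_signal(reg, treat, inp), 5.0)

  # floor at zero when input exceeds treatment
  expect_equal(quantify_domain_signal(reg, inp, treat), 0)

  # doubling library size and depth together leaves the signal unchanged
  treat2 <- toy_track(chrom = "c", start = 0, end = 10000, value = 0.2,
                      total_mapped = 2e7)
  inp2 <- toy_track(chrom = "c", start = 0, end = 10000, value = 0.1,
                    total_mapped = 2e7)
  expect_equal(quantify_domain_signal(reg, treat2, inp2), 5.0)
  expect_error(quantify_domain_signal(reg, toy_track(chrom = "c", start = 0,
                                                     end = 1, value = 1,
                                                     total_mapped = NA), inp),
               "total_mapped")
})

test_that("classify_domains applies the top-5%-and-50kb rule", {
  dom <- data.frame(chrom = "chr1", start = (0:99) * 2e6,
                    end = (0:99) * 2e6 + (1:100) * 1000)
  dom$breadth <- dom$end - dom$start
  cd <- classify_domains(dom, calling_params(seed = 3))
  expect_equal(sort(cd$breadth[cd$class_label == "grand"]),
               c(96, 97, 98, 99, 100) * 1000)
  expect_equal(sort(cd$breadth[cd$class_label == "narrow"]), (1:5) * 1000)
  expect_equal(sum(cd$is_control), 5)
  expect_true(all(cd$class_label[cd$is_control] == "typical"))
  th <- attr(cd, "thresholds")
  expect_equal(th$n_grand, 5)

  # the 50 kb floor bites: breadths 1..100 in *hundreds* of bp
  dom2 <- data.frame(chrom = "chr1", start = (0:99) * 2e6,
                     end = (0:99) * 2e6 + (1:100) * 100)
  dom2$breadth <- dom2$end - dom2$start
  cd2 <- classify_domains(dom2, calling_params(seed = 3))
  expect_equal(sum(cd2$class_label == "grand"), 0)
})

test_that("classify_domains caps ties at 5% with a warning", {
  dom <- data.frame(chrom = "chr1", start = (0:99) * 2e6,
                    end = (0:99) * 2e6 + 60000)
  dom$breadth <- dom$end - dom$start
  w <- testthat::capture_warnings(
    cd <- classify_domains(dom, calling_params(seed = 1)))
  expect_true(any(grepl("capping", w)))  # both cut-offs tie on equal breadths
  expect_equal(sum(cd$class_label == "grand"), 5)
  expect_true(all(cd$breadth[cd$class_label == "grand"] > 50000))
})

test_that("classification invariants hold on random instances", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(40:200, 1)
    b <- round(rlnorm(n, log(8000), 1.2))
    dom <- data.frame(chrom = "chr1", start = cumsum(b + 1e4) - b)
    dom$end <- dom$start + b
    dom$breadth <- b
    cd <- suppressWarnings(classify_domains(dom, calling_params(seed = i)))
    g <- cd$class_label == "grand"
    expect_lte(sum(g), ceiling(0.05 * n))
    if (any(g)) expect_gt(min(cd$breadth[g]), 50000)
    expect_false(any(cd$is_control & cd$class_label != "typical"))
  }
})

test_that("metagene_matrix profiles flat and step tracks correctly", {
  dom <- data.frame(chrom = "c", start = c(10000, 50000),
                    end = c(20000, 80000))
  flat <- toy_track(chrom = "c", start = 0, end = 1e5, value = 3)
  m <- metagene_matrix(dom, flat, flank = 3000, body_bins = 10,
                       flank_bins = 4)
  expect_equal(dim(m), c(2, 18))
  expect_true(all(m == 3))

  # step: value only inside the domain
  step <- toy_track(chrom = "c", start = 10000, end = 20000, value = 2)
  m2 <- metagene_matrix(dom[1, ], step, flank = 3000, body_bins = 10,
                        flank_bins = 4)
  expect_equal(unname(m2[1, ]), c(rep(0, 4), rep(2, 10), rep(0, 4)))

  # flank truncation at chromosome start is recorded, not fatal
  edge <- data.frame(chrom = "c", start = 0, end = 5000)
  m3 <- metagene_matrix(edge, flat, flank = 3000, body_bins = 5,
                        flank_bins = 3)
  expect_equal(attr(m3, "truncated"), 1L)
  expect_true(all(is.na(m3[1, 1:3])))
})

test_that("domains BED round-trips through write/read", {
  dom <- data.frame(chrom = "chr1", start = (0:39) * 1e6,
                    end = (0:39) * 1e6 + seq(2000, 80000, length.out = 40))
  dom$breadth <- dom$end - dom$start
  dom$signal <- seq(1, 5, length.out = 40)
  cd <- classify_domains(dom, calling_params(seed = 2))
  p <- withr::local_tempfile(fileext = ".bed")
  write_domains_bed(cd, p)
  back <- read_domains_bed(p)
  expect_equal(back$start, cd$start)
  expect_equal(sum(back$class_label == "grand"),
               sum(cd$class_label == "grand"))
  expect_equal(sum(back$is_control), sum(cd$is_control))
})
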