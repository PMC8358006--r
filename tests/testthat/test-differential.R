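test_that("gene_binned_profile is strand-oriented and bins steps", {
  g <- toy_genes("c", c(10000, 10000), c(20000, 20000), c("+", "-"))
  flat <- toy_track(chrom = "c", start = 0, end = 40000, value = 4)
  m <- gene_binned_profile(g, flat, body_bins = 10, flank = 2000,
                           flank_bins = 5)
  expect_equal(dim(m), c(2, 20))
  expect_true(all(m == 4))

  # step rising downstream: minus-strand profile is the reverse
  step <- coverage_track(data.frame(chrom = "c", start = c(0, 15000),
                                    end = c(15000, 40000), value = c(1, 9)))
  m2 <- gene_binned_profile(g, step, body_bins = 10, flank = 2000,
                            flank_bins = 5)
  expect_equal(unname(m2[1, ]), rev(unname(m2[2, ])))
  # body bins left of the step carry 1, right of it 9
  expect_equal(unname(m2[1, 6:10]), rep(1, 5))
  expect_equal(unname(m2[1, 12:20]), rep(9, 9))
})

test_that("classify_h3k27me3_change applies the 2-fold rule with pseudocount", {
  # hand arithmetic: log2(1.25 / 4.25) = -1.766 -> loss
  r <- classify_h3k27me3_change(c(a = 4), c(a = 1))
  expect_equal(r$log2_signal_fc, log2(1.25 / 4.25))
  expect_equal(r$k27_class, "loss")

  r2 <- classify_h3k27me3_change(c(a = 3, b = 0.1), c(a = 3, b = 0.1))
  expect_equal(r2$k27_class, c("stable", "stable"))
  expect_error(classify_h3k27me3_change(c(-1), c(2)), ">= 0")
})

test_that("condition swap maps loss to gain exactly (antisymmetry)", {
  set.seed(12)
  sn <- rexp(500, 1 / 5)
  st <- sn * 2^rnorm(500, 0, 1.5)
  fwd <- classify_h3k27me3_change(sn, st)
  rev <- classify_h3k27me3_change(st, sn)
  expect_equal(fwd$log2_signal_fc, -rev$log2_signal_fc)
  expect_equal(fwd$k27_class == "loss", rev$k27_class == "gain")
  expect_equal(fwd$k27_class == "stable", rev$k27_class == "stable")
})

test_that("integrate_expression_changes applies the DE gates", {
  k27 <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                    signal_normal = 4, signal_tumor = 1,
                    log2_signal_fc = c(-2, -2, 2, 2, 0),
                    k27_class = c("loss", "loss", "gain", "gain", "stable"))
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   log2fc = c(2, 2, -3, -0.5), fdr = c(0.01, 0.2, 0.01, 0.01))
  calls <- integrate_expression_changes(k27, de)
  expect_equal(calls$activation_class,
               c("activated",  # loss + up at FDR 0.01
                 "loss_only",  # loss + up but FDR 0.2 fails the gate
                 "silenced",   # gain + down
                 "gain_only",  # gain, |log2fc| below 1
                 "stable"))
  # gene e missing from the DE table keeps the k27-only label
  expect_true(is.na(calls$expr_log2fc[5]))

  dup <- rbind(de, data.frame(gene_id = "a", log2fc = 0, fdr = 1))
  expect_error(integrate_expression_changes(k27, dup), "duplicate")
})

test_that("internal DE mode round-trips through the external path", {
  set.seed(3)
  counts <- matrix(rnbinom(300, size = 10, mu = rep(c(20, 200, 20), each = 100)),
                   ncol = 12, dimnames = list(sprintf("g%d", 1:25), NULL))
  cond <- rep(c("normal", "tumor"), each = 6)
  k27 <- data.frame(gene_id = rownames(counts), signal_normal = 4,
                    signal_tumor = 1, log2_signal_fc = -2, k27_class = "loss")
  internal <- integrate_expression_changes(k27, replicate_counts = counts,
                                           condition = cond)
  external_tab <- gsdtools:::internal_de_table(counts, cond)
  external <- integrate_expression_changes(k27, de_table = external_tab)
  expect_equal(internal$activation_class, external$activation_class)
  expect_equal(internal$expr_log2fc, external$expr_log2fc)
})

test_that("activation percentages are self-consistent and match the ledger", {
  p <- activation_percentages(844, 557, 155, 208, 30)
  expect_equal(p$loss_pct, round(100 * 557 / 844, 1))
  expect_equal(p$activated_of_loss_pct, round(100 * 208 / 557, 1))
  expect_error(activation_percentages(10, 8, 5, 2, 1), "n_loss")
})

test_that("activation_summary computes counts, correlation and shift", {
  set.seed(6)
  n <- 60
  calls <- data.frame(gene_id = sprintf("g%d", 1:n),
                      log2_signal_fc = c(rep(-2, 30), rep(0, 30)),
                      k27_class = c(rep("loss", 30), rep("stable", 30)),
                      expr_log2fc = c(rnorm(30, 2), rnorm(30, 0)),
                      expr_fdr = rep(0.01, n))
  calls$activation_class <- ifelse(calls$k27_class == "loss" &
                                     calls$expr_log2fc > 1 &
                                     calls$expr_fdr < 0.05,
                                   "activated",
                                   ifelse(calls$k27_class == "loss",
                                          "loss_only", "stable"))
  s <- activation_summary(calls, background_log2fc = rnorm(200))
  p <- s$percentages
  expect_equal(p$loss_pct, round(100 * p$n_loss / p$n_total, 1))
  expect_equal(p$activated_of_loss_pct,
               round(100 * p$n_activated / p$n_loss, 1))
  expect_lt(s$correlation$r, 0)       # loss genes are the upregulated ones
  expect_lt(s$shift_test$p_value, 1e-6)
  expect_equal(nrow(s$cumulative), n)
  expect_equal(s$cumulative$cum_fraction[n], 1)

  # all stable: zero percentages, correlation skipped
  st <- calls
  st$k27_class <- "stable"; st$activation_class <- "stable"
  st$log2_signal_fc <- 0
  s2 <- activation_summary(st)
  expect_equal(s2$percentages$loss_pct, 0)
  expect_null(s2$correlation)
})

test_that("region_mark_profiles separates promoter and body methylation", {
  g <- toy_genes("c", c(20000, 60000), c(40000, 80000), c("+", "-"))
  flat <- function(v) coverage_track(data.frame(chrom = "c", start = 0,
                                                end = 1e5, value = v),
                                     value_bounds = c(0, 1))
  tracks <- list(h3k4me3 = list(normal = toy_track(chrom = "c", start = 0,
                                                   end = 1e5, value = 1),
                                tumor = toy_track(chrom = "c", start = 0,
                                                  end = 1e5, value = 2)))
  # uniform methylation in both conditions: deltas are zero
  r0 <- region_mark_profiles(g, tracks, methylation = list(normal = flat(0.5),
                                                           tumor = flat(0.5)))
  expect_equal(r0$methylation$mean_delta_body, 0)
  expect_equal(r0$methylation$mean_delta_promoter, 0)
  expect_false(r0$methylation$body_hyper_no_promoter_hypo)
  expect_equal(unname(r0$profiles$h3k4me3$tumor),
               rep(2, 80))

  # +0.2 beta over gene bodies only (2 kb past each TSS)
  body_runs <- data.frame(chrom = "c",
                          start = c(0, 22000, 40000, 60000, 78000),
                          end = c(22000, 40000, 60000, 78000, 1e5),
                          value = c(0.4, 0.6, 0.4, 0.6, 0.4))
  r1 <- region_mark_profiles(g, tracks,
                             methylation = list(normal = flat(0.4),
                                                tumor = coverage_track(
                                                  body_runs,
                                                  value_bounds = c(0, 1))))
  expect_equal(r1$methylation$mean_delta_body, 0.2, tolerance = 1e-6)
  expect_equal(r1$methylation$mean_delta_promoter, 0, tolerance = 1e-6)
  expect_true(r1$methylation$body_hyper_no_promoter_hypo)

  # a missing condition drops that mark with a warning
  expect_warning(r2 <- region_mark_profiles(
    g, list(h3k4me1 = list(normal = tracks$h3k4me3$normal))),
    "missing condition")
  expect_null(r2$profiles$h3k4me1)
})
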