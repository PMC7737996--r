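test_that("expression ratios follow the square-root level definition", {
  # areas 14400 vs 10000 -> levels 120 vs 100 -> 120.0%
  expect_equal(expression_ratio(to_level(14400), to_level(10000)), 120)
  expect_equal(expression_ratio(55, 55), 100)
  expect_error(expression_ratio(10, 0), "undefined ratio")
})

test_that("replicate aggregation follows the SD-convergence stopping rule", {
  # worked stream: (100, 110) has sd 7.07 > 5, adding 105 reaches sd 5.0
  agg <- aggregate_replicates(c(100, 110, 105, 999, 999, 999))
  expect_equal(agg$n, 3L)
  expect_equal(agg$mean, 105)
  expect_equal(agg$sd, 5)
  expect_true(agg$converged)
  expect_equal(agg$se, 5 / sqrt(3), tolerance = 1e-12)
  expect_equal(round(agg$se, 3), 2.887)

  # immediate convergence stops at the minimum
  agg <- aggregate_replicates(c(100, 100, 50, 50))
  expect_equal(agg$n, 2L)
  expect_true(agg$converged)

  # never-converging streams cap at six runs, flagged unconverged
  agg <- aggregate_replicates(c(100, 150, 50, 200, 0.1, 300))
  expect_equal(agg$n, 6L)
  expect_false(agg$converged)

  expect_error(aggregate_replicates(100), "exhausted")
})

test_that("aggregation bounds and convergence flag hold for random streams", {
  set.seed(1301)
  for (i in 1:200) {
    ratios <- 100 * rlnorm(6, sdlog = runif(1, 0, 0.15))
    agg <- aggregate_replicates(ratios)
    expect_gte(agg$n, 2L)
    expect_lte(agg$n, 6L)
    expect_identical(agg$converged, agg$sd <= 5)
    expect_lte(agg$se, agg$sd)
    expect_equal(agg$mean, mean(ratios[seq_len(agg$n)]))
  }
})

test_that("change classification maps deviations to the four bins", {
  expect_equal(classify_change(129.3)[c("bin", "direction")],
               list(bin = "marked", direction = "up"))
  expect_equal(classify_change(84.8)[c("bin", "direction")],
               list(bin = "significant", direction = "down"))
  # boundaries belong to the larger-magnitude bin
  expect_equal(classify_change(95)$bin, "slight")
  expect_equal(classify_change(110)$bin, "significant")
  expect_equal(classify_change(120)$bin, "marked")
  expect_equal(classify_change(100)$direction, "none")
  expect_equal(classify_change(104.99)$bin, "minimal")
})

test_that("classification partitions every ratio consistently with |delta|", {
  ratios <- seq(1, 260, by = 0.25)
  bins <- vapply(ratios, function(r) classify_change(r)$bin, character(1))
  mags <- abs(ratios - 100)
  expected <- cut(mags, c(-Inf, 5, 10, 20, Inf), right = FALSE,
                  labels = c("minimal", "slight", "significant", "marked"))
  expect_identical(bins, as.character(expected))
  # order-consistency: bin index is monotone in |delta|
  expect_true(all(diff(as.integer(expected)[order(mags)]) >= 0))
})

test_that("housekeeping QC passes within tolerance and names offenders", {
  hk <- c("alpha-tubulin", "beta-actin", "GAPDH")
  prof <- data.frame(protein = hk, timepoint_h = 8,
                     ratio_percent = c(104, 97, 100))
  qc <- housekeeping_qc(prof, hk)
  expect_true(qc$pass)
  expect_equal(qc$offenders, "")

  prof$ratio_percent <- c(93, 100, 101)
  qc <- housekeeping_qc(prof, hk)
  expect_false(qc$pass)
  expect_equal(qc$offenders, "alpha-tubulin")

  expect_error(housekeeping_qc(prof[1:2, ], hk), "missing GAPDH")
})

test_that("extremum change takes the largest deviation, earliest tie", {
  ex <- extremum_change(c(121.5, 113.0, 112.2), c(8, 16, 24))
  expect_equal(ex$delta_percent, 21.5)
  expect_equal(ex$timepoint_h, 8)

  ex <- extremum_change(c(100, 100, 100), c(8, 16, 24))
  expect_equal(ex$delta_percent, 0)
  expect_equal(ex$timepoint_h, 8)

  # largest magnitude wins regardless of sign, ties to the earliest
  ex <- extremum_change(c(85, 115), c(16, 24))
  expect_equal(ex$delta_percent, -15)
  expect_equal(ex$timepoint_h, 16)

  expect_equal(extremum_change(90, 24)$delta_percent, -10)
  expect_error(extremum_change(numeric(0), numeric(0)), "no timepoints")
})

test_that("proliferation index reproduces ratios of the mean counts", {
  means <- c(65.9, 63.2, 56.4, 51.7)
  tab <- data.frame(timepoint_h = rep(c(0, 8, 16, 24), each = 3),
                    count = rep(means, each = 3))
  idx <- proliferation_index(tab)
  expect_equal(round(idx$index_percent, 1), c(100, 95.9, 85.6, 78.5))
  expect_equal(idx$sd, rep(0, 4))

  same <- data.frame(timepoint_h = rep(c(0, 8, 16, 24), each = 2),
                     count = 60)
  expect_equal(proliferation_index(same)$index_percent, rep(100, 4))

  one <- data.frame(timepoint_h = c(0, 8, 16, 24), count = c(60, 50, 40, 30))
  idx <- proliferation_index(one)
  expect_equal(idx$n_images, rep(1L, 4))
  expect_equal(idx$sd, rep(0, 4))

  expect_error(proliferation_index(data.frame(timepoint_h = 8, count = 1)),
               "0 h")
})

test_that("profiling recovers simulated fold changes through the pipeline", {
  reg <- mini_panel()
  folds <- data.frame(antibody = c("Ki-67", "Ki-67", "cMyc"),
                      timepoint_h = c(8, 24, 16),
                      level_fold = c(1.2, 0.8, 1.1))
  tr <- simulation_truth(reg, fold_table = folds, replicate_cv = 0.02)
  ex <- simulate_experiment(reg, tr, n_replicates = 4, seed = 17,
                            step_min = 0.02)
  res <- profile_experiment(ex, reg)

  expect_setequal(unique(res$protein), reg$records$name)
  truth_ratio <- 100 * tr$level_fold[match(
    paste(res$protein, res$timepoint_h),
    paste(tr$antibody, tr$timepoint_h))]
  expect_lt(mean(abs(res$ratio_percent - truth_ratio)), 2)
  expect_true(all(res$n_replicates >= 2 & res$n_replicates <= 6))
  expect_true(all(res$converged == (res$sd <= 5)))
  expect_equal(nrow(attr(res, "skipped")), 0L)
  expect_true(all(attr(res, "qc")$pass))
})

test_that("clamped control peaks are skipped, not fatal", {
  reg <- mini_panel()
  tr <- simulation_truth(reg, antibodies = c("Ki-67", "PCNA",
                                             housekeeping_proteins(reg)),
                         replicate_cv = 0, noise_sd_mAU = 0)
  ex <- simulate_experiment(reg, tr, n_replicates = 2, seed = 2,
                            step_min = 0.02)
  # overwrite PCNA control traces with background-only signal so the net
  # area clamps to zero
  ex$chromatograms <- lapply(ex$chromatograms, function(ch) {
    if (ch$antibody == "PCNA" && ch$condition == "control") {
      ch$absorbance_mAU <- ex$negative_controls[[ch$batch]]$absorbance_mAU
    }
    ch
  })
  res <- profile_experiment(ex, reg)
  skipped <- attr(res, "skipped")
  expect_false("PCNA" %in% res$protein)
  expect_true(all(skipped$antibody == "PCNA"))
  expect_equal(nrow(skipped), 6L)   # 3 timepoints x 2 replicates
  expect_true("Ki-67" %in% res$protein)
})
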