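test_that("baseline estimation recovers flat and drifting baselines", {
  flat <- simulate_chromatogram(list(), baseline_offset = 2, noise_sd = 0,
                                seed = 1)
  bl <- estimate_baseline(flat, c(11, 13))
  expect_equal(bl$slope, 0)
  expect_equal(bl$offset, 2)

  drift <- simulate_chromatogram(peak_spec(12, 0.1, 150.4),
                                 baseline_slope = 0.3,
                                 baseline_offset = 1.5, noise_sd = 0,
                                 seed = 1)
  bl <- estimate_baseline(drift, c(11, 13))
  expect_equal(bl$slope, 0.3, tolerance = 0.01)
  expect_equal(bl$offset, 1.5, tolerance = 0.01)

  # a peak fully inside the window does not bias the flanks
  peak_only <- simulate_chromatogram(peak_spec(12, 0.1, 150.4),
                                     noise_sd = 0, seed = 1)
  bl <- estimate_baseline(peak_only, c(11, 13))
  expect_equal(bl$slope, 0, tolerance = 1e-6)
  expect_equal(bl$offset, 0, tolerance = 1e-6)

  expect_error(estimate_baseline(flat, c(0, 2)), "touches the trace edge")
})

test_that("peak-window detection brackets the dominant peak", {
  ch <- simulate_chromatogram(peak_spec(12, 0.1, 150.4), noise_sd = 0.05,
                              seed = 2)
  w <- detect_peak_window(ch)
  expect_lte(w[1], 11.6)
  expect_gte(w[2], 12.4)

  flat <- simulate_chromatogram(list(), noise_sd = 0.2, seed = 3)
  expect_error(detect_peak_window(flat), "no peak detected")

  two <- simulate_chromatogram(list(peak_spec(8, 0.1, 10),
                                    peak_spec(20, 0.1, 100)),
                               noise_sd = 0, seed = 1)
  w <- detect_peak_window(two)
  expect_true(w[1] > 18 && w[2] < 22)   # selects the larger peak
})

test_that("trapezoidal integration matches the analytic Gaussian area", {
  area <- gaussian_area(10, 0.1)   # 150.398... mAU*s
  ch <- simulate_chromatogram(peak_spec(12, 0.1, area), noise_sd = 0,
                              seed = 1)
  got <- integrate_peak(ch, c(12 - 0.5, 12 + 0.5),       # +/- 5 sigma
                        list(slope = 0, offset = 0))
  expect_lt(abs(got - area) / area, 0.005)

  flat <- simulate_chromatogram(list(), noise_sd = 0, seed = 1)
  expect_equal(integrate_peak(flat, c(10, 14), list(slope = 0, offset = 0)),
               0)

  # linearity in the signal
  ch2 <- ch
  ch2$absorbance_mAU <- 2 * ch$absorbance_mAU
  expect_equal(integrate_peak(ch2, c(11.5, 12.5), list(slope = 0, offset = 0)),
               2 * integrate_peak(ch, c(11.5, 12.5), list(slope = 0, offset = 0)))

  expect_error(integrate_peak(ch, c(12, 12.015), list(slope = 0, offset = 0)),
               "fewer than 3 samples")
})

test_that("areas are additive over adjacent windows", {
  ch <- simulate_chromatogram(peak_spec(12, 0.2, 90, 0.1), noise_sd = 0,
                              seed = 1)
  bl <- list(slope = 0, offset = 0)
  left <- integrate_peak(ch, c(10, 12), bl)
  right <- integrate_peak(ch, c(12, 14), bl)
  whole <- integrate_peak(ch, c(10, 14), bl)
  expect_equal(left + right, whole, tolerance = 1e-10)
})

test_that("background subtraction clamps at zero with a flag", {
  s <- subtract_negative_control(150.4, 20.4)
  expect_equal(s$net_area, 130)
  expect_false(s$clamped)

  s <- subtract_negative_control(10, 12)
  expect_equal(s$net_area, 0)
  expect_true(s$clamped)

  expect_equal(subtract_negative_control(77.7, 0)$net_area, 77.7)
  expect_error(subtract_negative_control(-1, 0), "non-negative")
})

test_that("square-root normalization is exact and monotone", {
  expect_equal(to_level(2500), 50)
  expect_equal(to_level(0), 0)
  a <- seq(0, 500, by = 25)
  expect_true(all(diff(to_level(a)) > 0))
  expect_equal(to_level(a)^2, a)
  expect_error(to_level(-1), ">= 0")
})

test_that("the noiseless pipeline recovers simulator areas within 1%", {
  for (tau in c(0, 0.05, 0.2)) {
    for (area in c(40, 150.4, 900)) {
      ch <- simulate_chromatogram(peak_spec(12, 0.1, area + 25, tau),
                                  baseline_slope = 0.05,
                                  baseline_offset = 2, noise_sd = 0,
                                  seed = 1)
      neg <- simulate_chromatogram(peak_spec(12, 0.1, 25, tau),
                                   baseline_slope = 0.05,
                                   baseline_offset = 2, noise_sd = 0,
                                   seed = 1)
      q <- quantify_chromatogram(ch, neg)
      expect_lt(abs(q$net_area_mAU_s - area) / area, 0.01)
      expect_equal(q$level^2, q$net_area_mAU_s, tolerance = 1e-12)
      expect_false(q$clamped)
    }
  }
})

test_that("a common detector gain leaves expression ratios unchanged", {
  ch_c <- simulate_chromatogram(peak_spec(12, 0.1, 10025, 0.05),
                                baseline_offset = 1, noise_sd = 0.2,
                                seed = 4)
  ch_t <- simulate_chromatogram(peak_spec(12, 0.1, 14425, 0.05),
                                baseline_offset = 1, noise_sd = 0.2,
                                seed = 5)
  neg <- simulate_chromatogram(peak_spec(12, 0.1, 25, 0.05),
                               baseline_offset = 1, noise_sd = 0.2,
                               seed = 6)
  ratio_for <- function(gain) {
    scale <- function(ch) { ch$absorbance_mAU <- gain * ch$absorbance_mAU; ch }
    qc <- quantify_chromatogram(scale(ch_c), scale(neg))
    qt <- quantify_chromatogram(scale(ch_t), scale(neg))
    expression_ratio(qt$level, qc$level)
  }
  base <- ratio_for(1)
  for (g in c(0.5, 2, 10)) {
    expect_equal(ratio_for(g), base, tolerance = 1e-9)
  }
})
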