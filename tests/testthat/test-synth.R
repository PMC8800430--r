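# Synthetic-data generators: zero-noise exactness, seed determinism, and
# truth echoes that match the requested configurations.

test_that("zero-noise SAXS curve equals the forward model exactly", {
  g <- generate_saxs_curve(synth_config("saxs", seed = 3, noise = 0,
                                        truth = space_upper()))
  expect_identical(g$curve$intensity,
                   unified_model_intensity(space_upper(), g$curve$q))
  expect_null(g$curve$sigma)
})

test_that("SAXS noise has the configured fractional spread and sigma echo", {
  g <- generate_saxs_curve(synth_config("saxs", seed = 1, noise = 0.02,
                                        truth = space_upper()))
  expect_length(g$curve$q, 200L)
  resid <- g$curve$intensity / g$model_intensity - 1
  expect_gte(sd(resid), 0.015)   # direct moment check of generated residuals
  expect_lte(sd(resid), 0.025)
  expect_equal(g$curve$sigma, 0.02 * g$model_intensity)
})

test_that("identical SAXS configurations give bit-identical output", {
  cfg <- synth_config("saxs", seed = 11, noise = 0.05, truth = space_upper())
  g1 <- generate_saxs_curve(cfg)
  g2 <- generate_saxs_curve(cfg)
  expect_identical(g1$curve$intensity, g2$curve$intensity)
})

test_that("negative-intensity draws are regenerated with truncated deviates", {
  # background-dominated flat curve + huge fractional noise forces negatives
  p <- unified_params(1, 0.01, 0, 30, 2, 0.001, 0, 5, 2)
  expect_warning(
    g <- generate_saxs_curve(synth_config("saxs", seed = 2, noise = 0.5,
                                          truth = p)),
    "truncated")
  expect_gt(length(g$truncated), 0)
  # the offending points are deterministically regenerated from the same
  # stream with the deviate clipped to [-5, 5]; never clamped to zero
  eps <- local({set.seed(2); rnorm(200)})
  eps_clip <- pmax(pmin(eps, 5), -5)
  expect_equal(g$curve$intensity[g$truncated],
               (g$model_intensity * (1 + 0.5 * eps_clip))[g$truncated])
  expect_false(any(g$curve$intensity == 0))
})

test_that("peak-free zero-noise WAXS profile equals its background", {
  g <- generate_waxs_profile(synth_config(
    "waxs", noise = 0,
    truth = list(peaks = NULL, background = c(40, 8, 0.9))))
  expect_equal(g$profile$intensity, g$background)
})

test_that("a generated WAXS peak integrates to its configured area", {
  g <- generate_waxs_profile(synth_config(
    "waxs", noise = 0,
    truth = list(peaks = data.frame(center = 15.6, fwhm = 0.35, area = 200),
                 background = c(40, 8, 0.9))))
  excess <- g$profile$intensity - g$background
  q <- g$profile$q
  trapezoid <- sum(diff(q) * (head(excess, -1) + tail(excess, -1)) / 2)
  expect_lt(abs(trapezoid - 200) / 200, 0.005)
})

test_that("cellulose II peak centers are generated exactly as requested", {
  tr <- waxs_truth()
  g <- generate_waxs_profile(synth_config("waxs", noise = 0, truth = tr))
  expect_identical(g$truth$center, tr$peaks$center)
  # and the requested centers are the canonical cellulose II positions
  expect_equal(round(g$truth$center[1], 2), 8.69, tolerance = 1e-8)
})

test_that("nearly coincident WAXS peaks are flagged unresolvable", {
  tr <- list(peaks = data.frame(center = c(10, 10.05), fwhm = c(0.4, 0.4),
                                area = c(50, 50)),
             background = c(40, 8, 0.9))
  expect_warning(g <- generate_waxs_profile(synth_config("waxs", truth = tr)),
                 "unresolvable")
  expect_true(g$unresolvable)
})

test_that("MALDI comb has one peak per DP with exact 162.14 Da spacing", {
  g <- generate_maldi_spectrum(synth_config("maldi", noise = 0))
  expect_identical(g$truth$dp, 4:11)          # 8 peak positions
  expect_equal(diff(g$truth$peak_mz), rep(162.14, 7))
  expect_equal(g$truth$peak_mz[1], 162.14 * 4 + 41.0)
})

test_that("envelope-weighted mean of generated peak heights recovers mean DP", {
  g <- generate_maldi_spectrum(synth_config("maldi", noise = 0,
                                            truth = list(mean_dp = 6.9)))
  wm <- sum(g$truth$dp * g$truth$peak_height) / sum(g$truth$peak_height)
  expect_lt(abs(wm - 6.9), 0.01)  # closed-form weighted-mean oracle
})

test_that("empty DP range is rejected", {
  expect_error(generate_maldi_spectrum(
    synth_config("maldi", truth = list(dp_range = c(8L, 4L)))), "empty")
})

test_that("a horizontal ribbon renders with exact column thickness", {
  g <- generate_ribbon_image(single_ribbon_config(11))
  cols <- colSums(g$image$pixels > 0.5)
  interior <- cols[cols > 0]
  expect_true(all(interior == 11))
})

test_that("drawn lognormal widths have the configured mean", {
  cfg <- synth_config("ribbon_image", seed = 4,
                      truth = list(n_ribbons = 200L))
  g <- generate_ribbon_image(cfg)
  expect_length(g$truth_widths_um, 200L)
  expect_lt(abs(mean(g$truth_widths_um) - 0.254) / 0.254, 0.05)
})

test_that("ribbon images are seed-deterministic and sub-3px widths rejected", {
  cfg <- synth_config("ribbon_image", seed = 9, truth = list(n_ribbons = 30L))
  expect_identical(generate_ribbon_image(cfg)$image$pixels,
                   generate_ribbon_image(cfg)$image$pixels)
  expect_error(generate_ribbon_image(single_ribbon_config(2.5)),
               "unmeasurable")
})

test_that("grid axes must be increasing and images at least 64 px", {
  expect_error(synth_config("saxs", grid = list(qmin = 2, qmax = 1)),
               "increasing")
  expect_error(synth_config("ribbon_image", grid = list(size = c(32L, 128L))),
               "64")
})
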