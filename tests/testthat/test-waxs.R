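# WAXS: d-spacing and angle conversions, smooth-background estimation,
# Gaussian peak deconvolution, reflection assignment, position averages.

test_that("d = 2 pi / Q reproduces the cellulose II conversions", {
  expect_equal(round(q_to_d(8.69), 2), 7.23)
  expect_equal(round(q_to_d(15.6), 2), 4.03)
  expect_equal(q_to_d(2 * pi), 10)
  expect_error(q_to_d(0), "q must")
  expect_error(q_to_d(-1), "q must")
})

test_that("q_to_d and d_to_q are exact inverses", {
  q <- c(0.5, 8.69, 14.1, 15.6, 30)
  expect_lt(max(abs(d_to_q(q_to_d(q)) - q) / q), 1e-12)
})

test_that("scattering-angle conversion matches the frozen trig oracle", {
  expect_equal(q_to_two_theta(0), 0)
  expect_equal(q_to_two_theta(15.6, instrument_geometry(wavelength = 0.92)),
               13.11607471607683, tolerance = 1e-12)
  # doubling the wavelength doubles sin(theta) exactly
  th1 <- q_to_two_theta(10, instrument_geometry(0.92))
  th2 <- q_to_two_theta(10, instrument_geometry(1.84))
  expect_equal(sin(th2 / 2 * pi / 180), 2 * sin(th1 / 2 * pi / 180),
               tolerance = 1e-12)
  expect_error(q_to_two_theta(200, instrument_geometry(10)), "exceeds 1")
})

test_that("background reproduces a peak-free smooth profile", {
  g <- generate_waxs_profile(synth_config(
    "waxs", noise = 0, truth = list(peaks = NULL,
                                    background = c(40, 8, 0.9))))
  wins <- cellulose_peak_windows(qlim = g$profile)
  bg <- estimate_smooth_background(g$profile, wins)
  rms <- sqrt(mean((bg$intensity - g$profile$intensity)^2))
  expect_lt(rms, 0.005 * mean(g$profile$intensity))
})

test_that("background under three peaks stays within 2% of the truth", {
  g <- generate_waxs_profile(synth_config("waxs", seed = 2, noise = 0.01,
                                          truth = waxs_truth()))
  wins <- cellulose_peak_windows(qlim = g$profile)
  bg <- estimate_smooth_background(g$profile, wins)
  inside <- Reduce(`|`, lapply(wins, function(w)
    g$profile$q >= w[1] & g$profile$q <= w[2]))
  expect_lt(max(abs(bg$intensity[inside] - g$background[inside]) /
                  g$background[inside]), 0.02)
})

test_that("monotone input yields a monotone background", {
  g <- generate_waxs_profile(synth_config(
    "waxs", noise = 0, truth = list(peaks = NULL,
                                    background = c(40, 8, 0.9))))
  expect_true(all(diff(g$profile$intensity) > 0))  # rising water scattering
  bg <- estimate_smooth_background(g$profile,
                                   cellulose_peak_windows(qlim = g$profile))
  expect_true(all(diff(bg$intensity) >= 0))
})

test_that("insufficient out-of-window support is rejected", {
  g <- generate_waxs_profile(synth_config(
    "waxs", noise = 0, truth = list(peaks = NULL, background = c(1, 1))))
  expect_error(estimate_smooth_background(g$profile, list(c(5, 14.9))),
               "30%")
})

test_that("noise-free peak areas and widths are recovered within 1%", {
  tr <- waxs_truth()
  g <- generate_waxs_profile(synth_config("waxs", noise = 0, truth = tr))
  wins <- cellulose_peak_windows(qlim = g$profile)
  bg <- estimate_smooth_background(g$profile, wins)
  pf <- fit_peaks(g$profile, bg, wins)
  expect_lt(max(abs(pf$area - tr$peaks$area) / tr$peaks$area), 0.01)
  expect_lt(max(abs(pf$fwhm_q - tr$peaks$fwhm) / tr$peaks$fwhm), 0.01)
  expect_false(any(pf$absent))
})

test_that("1% noise keeps fitted centers within 0.05 nm^-1 of truth", {
  tr <- waxs_truth()
  g <- generate_waxs_profile(synth_config("waxs", seed = 3, noise = 0.01,
                                          truth = tr))
  wins <- cellulose_peak_windows(qlim = g$profile)
  bg <- estimate_smooth_background(g$profile, wins)
  pf <- fit_peaks(g$profile, bg, wins)
  expect_lt(max(abs(pf$center_q - tr$peaks$center)), 0.05)
})

test_that("a window with no peak is flagged absent with zero area", {
  g <- generate_waxs_profile(synth_config(
    "waxs", noise = 0,
    truth = list(peaks = data.frame(center = 15.6, fwhm = 0.35, area = 200),
                 background = c(40, 8, 0.9))))
  wins <- list(c(7.9, 9.5), c(14.8, 16))
  bg <- estimate_smooth_background(g$profile, wins)
  pf <- fit_peaks(g$profile, bg, wins)
  expect_true(pf$absent[1])
  expect_equal(pf$area[1], 0)
  expect_false(pf$absent[2])
})

test_that("peak area is invariant to a constant offset in both curves", {
  tr <- waxs_truth()
  g <- generate_waxs_profile(synth_config("waxs", seed = 4, noise = 0.01,
                                          truth = tr))
  wins <- cellulose_peak_windows(qlim = g$profile)
  bg <- estimate_smooth_background(g$profile, wins)
  pf0 <- fit_peaks(g$profile, bg, wins)
  up <- function(crv, c0) scattering_curve(crv$q, crv$intensity + c0)
  pf1 <- fit_peaks(up(g$profile, 123), up(bg, 123), wins)
  expect_equal(pf1$area, pf0$area, tolerance = 1e-8)
})

test_that("reflection assignment labels the cellulose II planes one-to-one", {
  pk <- data.frame(center_q = d_to_q(c(7.23, 4.45, 4.03)))
  asg <- assign_reflections(pk)
  expect_equal(asg$plane, c("1-10", "110", "020"))
  expect_equal(asg$d_ref, unname(cellulose_ii_dspacings()))
  expect_equal(nrow(assign_reflections(pk[0, , drop = FALSE])), 0L)
  far <- assign_reflections(data.frame(center_q = d_to_q(10)))
  expect_equal(far$plane, "unassigned")
})

test_that("position averages match the tabulated reporting convention", {
  expect_equal(summarize_positions(
    c(upper = 125, middle = 88.8, bottom = 93.9))$rounded, 103)
  expect_equal(summarize_positions(
    c(upper = 0.379, middle = 0.282, bottom = 0.296))$rounded, 0.319)
  expect_equal(summarize_positions(c(upper = 1, middle = 1, bottom = 1))$mean, 1)
  expect_error(summarize_positions(c(upper = 1, middle = 2)), "positions")
})
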