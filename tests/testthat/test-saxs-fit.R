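# Unified-model fitting, Kratky transform, reference subtraction, local
# power-law slopes and position averaging.

test_that("noiseless synthetic curve is recovered to well under 1%", {
  truth <- space_upper()
  g <- generate_saxs_curve(synth_config("saxs", noise = 0,
                                        grid = list(n = 300L), truth = truth))
  init <- perturb_params(truth, c(1.2, 0.8, 1.2, 0.85, 1.1, 1.2, 0.8, 1.15, 0.9))
  fit <- fit_unified_model(g$curve, init)
  est <- unlist(fit$params)
  expect_true(fit$converged)
  expect_lt(max(abs(est - unlist(truth)) / unlist(truth)), 0.01)
  expect_lt(fit$chi2_per_point, 1e-6)
})

test_that("2% noise fits reach the optimum and recover the lamellar radius", {
  truth <- space_upper()
  g <- generate_saxs_curve(synth_config("saxs", seed = 5, noise = 0.02,
                                        grid = list(n = 300L), truth = truth))
  init <- perturb_params(truth, c(0.9, 1.15, 0.85, 1.2, 0.95, 0.85, 1.2, 0.8, 1.1))
  fit <- fit_unified_model(g$curve, init, weighting = "sigma")
  # the fit must be at least as good as the generating truth: no local trap
  chi2_truth <- mean(((g$curve$intensity -
                         unified_model_intensity(truth, g$curve$q)) /
                        g$curve$sigma)^2)
  expect_lte(fit$chi2_per_point, chi2_truth)
  # Rg2 (the Kratky-peak level, well inside the measured window) is tight;
  # the bound allows for this realization's statistical error at the global
  # optimum. Rg1's Guinier knee sits at the very edge of the Q range, so
  # single-realization accuracy for both radii is assessed as a median over
  # replicates elsewhere.
  expect_lt(abs(fit$params$Rg2 - truth$Rg2) / truth$Rg2, 0.06)
  expect_true(all(is.finite(fit$stderr)))
})

test_that("a flat curve fits to its constant as pure background", {
  q <- 10^seq(-1, 1, length.out = 100)
  crv <- scattering_curve(q, rep(5, 100))
  init <- unified_params(4, 1, 0.01, 30, 2, 0.5, 0.01, 5, 2)
  fit <- fit_unified_model(crv, init, weighting = "none")
  expect_lt(abs(fit$params$background - 5) / 5, 0.01)
})

test_that("underdetermined or non-finite inputs are rejected", {
  q <- 10^seq(-1, 1, length.out = 100)
  short <- scattering_curve(q[1:10], rep(1, 10))
  expect_error(fit_unified_model(short, space_upper()), "50 points|decade")
  bad <- scattering_curve(q, c(rep(1, 99), NA))
  expect_error(fit_unified_model(bad, space_upper()), "non-finite")
})

test_that("Kratky transform multiplies by Q^2 and propagates sigma", {
  q <- seq(0.1, 2, length.out = 40)
  k <- kratky_transform(scattering_curve(q, rep(1, 40), sigma = rep(0.1, 40)))
  expect_equal(k$intensity, q^2)
  expect_equal(k$sigma, 0.1 * q^2)
})

test_that("Kratky maximum of a one-level Guinier curve sits at sqrt(3)/Rg", {
  rg <- 3.50
  q <- seq(0.05, 2.5, length.out = 2000)
  crv <- scattering_curve(q, 100 * exp(-q^2 * rg^2 / 3))
  k <- kratky_transform(crv)
  qmax <- q[which.max(k$intensity)]
  expect_lt(abs(qmax - sqrt(3) / rg), diff(q)[1] * 1.5)
  expect_equal(sqrt(3) / rg, 0.4949, tolerance = 2e-4)
})

test_that("Kratky value of the full model matches the frozen oracle at 0.9", {
  ev <- 0.9^2 * unified_model_intensity(ground_middle(), 0.9)
  expect_equal(ev, 3.079254575634645, tolerance = 1e-12)
})

test_that("subtracting a curve from itself gives zero; grids must match", {
  g <- generate_saxs_curve(synth_config("saxs", noise = 0,
                                        truth = space_upper()))
  d <- subtract_reference(g$curve, g$curve)
  expect_equal(d$intensity, rep(0, length(d$q)))
  shifted <- scattering_curve(g$curve$q * 1.0000001, g$curve$intensity)
  expect_error(subtract_reference(g$curve, shifted), "grid")
})

test_that("residual of two noiseless models equals the closed-form difference", {
  pa <- space_upper()
  pb <- perturb_params(pa, c(1, 1, 1, 1, 1, 0.5, 1, 1, 1))  # halved G2
  ga <- generate_saxs_curve(synth_config("saxs", noise = 0, truth = pa))
  gb <- generate_saxs_curve(synth_config("saxs", noise = 0, truth = pb))
  d <- subtract_reference(ga$curve, gb$curve)
  expect_equal(d$intensity,
               unified_model_intensity(pa, d$q) -
                 unified_model_intensity(pb, d$q))
  # sigma combines in quadrature
  sa <- scattering_curve(ga$curve$q, ga$curve$intensity,
                         sigma = rep(3, length(ga$curve$q)))
  sb <- scattering_curve(ga$curve$q, gb$curve$intensity,
                         sigma = rep(4, length(ga$curve$q)))
  expect_equal(subtract_reference(sa, sb)$sigma, rep(5, length(ga$curve$q)))
})

test_that("local power-law slope recovers exact exponents", {
  q <- 10^seq(-1.2, 0.2, length.out = 80)
  expect_equal(local_power_law_slope(
    scattering_curve(q, q^-2.30), 0.07, 0.5)$exponent, 2.30,
    tolerance = 1e-12)
  expect_equal(local_power_law_slope(
    scattering_curve(q, rep(3, 80)), 0.07, 0.5)$exponent, 0,
    tolerance = 1e-12)
})

test_that("model slope over the plate-scattering window matches the frozen regression oracle", {
  g <- generate_saxs_curve(synth_config("saxs", noise = 0,
                                        grid = list(n = 300L),
                                        truth = space_upper()))
  sl <- local_power_law_slope(g$curve, 0.07, 0.5)
  expect_equal(sl$n, 165L)
  expect_equal(sl$exponent, 2.354869626693309, tolerance = 1e-10)
})

test_that("position averages report mean +/- SEM with the n-1 convention", {
  a <- average_with_sem(c(6.48, 6.56, 6.78), digits = 2)
  expect_equal(a$mean_rounded, 6.61)
  expect_equal(a$sem_rounded, 0.09)
  b <- average_with_sem(c(6.22, 3.50, 4.00), digits = 2)
  expect_equal(b$mean_rounded, 4.57)
  expect_equal(b$sem_rounded, 0.84)
  cc <- average_with_sem(c(5, 5, 5))
  expect_equal(cc$mean, 5)
  expect_equal(cc$sem, 0)
  expect_error(average_with_sem(6.5), "at least 2")
})
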