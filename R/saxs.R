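#' Fit the two-level unified model to a SAXS curve
#'
#' Bounded Levenberg-Marquardt least squares (via \pkg{minpack.lm}) of the
#' unified Guinier/power-law model. Residuals are
#' \eqn{(I_{obs} - I_{model})/\sigma} when `weighting = "sigma"` and the
#' curve carries uncertainties, and \eqn{\log I_{obs} - \log I_{model}}
#' otherwise ("none"): the log form gives every decade of a
#' several-decade SAXS curve comparable leverage when no error model exists.
#' On reported non-convergence the fit is restarted up to 5 times from
#' deterministically perturbed initial values; the restart with the lowest
#' chi-square per point wins.
#'
#' The level ordering `Rg1 > Rg2` is enforced through box bounds: the default
#' bounds split the two radii at the geometric mean of their initial values.
#'
#' @param curve A [scattering_curve()] with at least 50 points spanning at
#'   least one decade in Q.
#' @param init A [unified_params()] starting point.
#' @param bounds Optional list with numeric vectors `lower` and `upper`
#'   named like the parameters; unnamed entries fall back to defaults.
#' @param weighting `"sigma"` (default when the curve has uncertainties) or
#'   `"none"`.
#' @param max_restarts Restarts attempted on non-convergence (default 5).
#'
#' @return An object of class `unified_fit` with elements `params`
#'   ([unified_params()]), `stderr` (named numeric), `chi2_per_point`,
#'   `residuals` (weighted), `converged`, `weighting`, and `niter`.
#' @export
#' @examples
#' truth <- unified_params(0.79, 3360, 0.62, 34.4, 2.78, 56.4, 1.32, 6.48, 2.71)
#' q <- 10^seq(log10(0.07), log10(2.5), length.out = 120)
#' crv <- scattering_curve(q, unified_model_intensity(truth, q))
#' fit <- fit_unified_model(crv, truth)
#' fit$chi2_per_point
fit_unified_model <- function(curve, init, bounds = NULL,
                              weighting = c("sigma", "none"),
                              max_restarts = 5L) {
  stopifnot(inherits(curve, "scattering_curve"), inherits(init, "unified_params"))
  weighting <- match.arg(weighting)
  if (weighting == "sigma" && is.null(curve$sigma)) weighting <- "none"
  if (any(!is.finite(curve$intensity)))
    stop("curve contains non-finite intensities")
  n <- length(curve$q)
  pnames <- c("background", "G1", "B1", "Rg1", "P1", "G2", "B2", "Rg2", "P2")
  if (n <= length(pnames))
    stop("fewer points than free parameters")
  if (n < 50L || max(curve$q) / min(curve$q) < 10)
    stop("fit needs >= 50 points spanning at least one decade in Q")
  if (weighting == "none" && any(curve$intensity <= 0))
    stop("log-intensity weighting needs strictly positive intensities")

  p0 <- unlist(init[pnames])
  gm_rg <- sqrt(p0[["Rg1"]] * p0[["Rg2"]])
  lower <- c(background = 0, G1 = 0, B1 = 0, Rg1 = gm_rg, P1 = 0.3,
             G2 = 0, B2 = 0, Rg2 = 0.1, P2 = 0.3)
  upper <- c(background = max(p0[["background"]] * 100, 10),
             G1 = p0[["G1"]] * 100, B1 = max(p0[["B1"]] * 100, 10),
             Rg1 = p0[["Rg1"]] * 10, P1 = 8,
             G2 = max(p0[["G2"]] * 100, 10), B2 = max(p0[["B2"]] * 100, 10),
             Rg2 = gm_rg, P2 = 8)
  if (!is.null(bounds)) {
    for (nm in names(bounds$lower)) lower[[nm]] <- bounds$lower[[nm]]
    for (nm in names(bounds$upper)) upper[[nm]] <- bounds$upper[[nm]]
  }
  p0 <- pmin(pmax(p0, lower), upper)

  model_at <- function(p) {
    pl <- as.list(p)
    pl$Rg1 <- max(pl$Rg1, pl$Rg2 * (1 + 1e-9))  # guard against bound-touching ties
    unified_model_intensity(do.call(unified_params, pl), curve$q)
  }
  resid_fn <- function(p) {
    m <- model_at(p)
    if (weighting == "sigma") (curve$intensity - m) / curve$sigma
    else log(curve$intensity) - log(pmax(m, .Machine$double.xmin))
  }

  run_once <- function(start) {
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  }

  best <- run_once(p0)
  tries <- 0L
  # two deterministic restarts are always taken (the landscape has local
  # minima in the Rg1/P1 trough); more follow while unconverged
  while (tries < max_restarts &&
         (tries < 2L || !(best$info %in% 1:4))) {
    tries <- tries + 1L
    # deterministic perturbation ladder, not RNG-dependent
    fac <- 1 + 0.13 * tries * rep_len(c(1, -1), length(p0)) *
      (-1)^(seq_along(p0) + tries)
    start <- pmin(pmax(p0 * fac, lower), upper)
    cand <- run_once(start)
    if (cand$deviance < best$deviance) best <- cand
  }
  fit <- best

  pe <- fit$par
  params <- do.call(unified_params, as.list(pe))
  se <- tryCatch({
    cf <- summary(fit)$coefficients
    stats::setNames(cf[, "Std. Error"], rownames(cf))
  }, error = function(e) stats::setNames(rep(NA_real_, length(pe)), names(pe)))
  resid <- resid_fn(pe)
  structure(list(params = params,
                 stderr = se[pnames],
                 chi2_per_point = sum(resid^2) / n,
                 residuals = resid,
                 converged = fit$info %in% 1:4,
                 weighting = weighting,
                 niter = fit$niter),
            class = "unified_fit")
}

#' @export
print.unified_fit <- function(x, ...) {
  cat(sprintf("unified two-level fit (%s-weighted): chi2/point = %.4g, %s\n",
              x$weighting, x$chi2_per_point,
              if (x$converged) "converged" else "NOT converged"))
  p <- unlist(x$params[c("background", "G1", "B1", "Rg1", "P1",
                         "G2", "B2", "Rg2", "P2")])
  for (nm in names(p))
    cat(sprintf("  %-10s %12.5g  +/- %.3g\n", nm, p[[nm]], x$stderr[[nm]]))
  invisible(x)
}

#' Kratky transform of a scattering curve
#'
#' Replaces the intensity by \eqn{Q^2 I(Q)} (uncertainties propagated as
#' \eqn{Q^2\sigma}). Guinier levels become peaks in this representation; a
#' pure one-level Guinier term with radius of gyration Rg peaks at
#' \eqn{Q = \sqrt{3}/Rg}.
#'
#' @param curve A [scattering_curve()].
#' @return A [scattering_curve()] holding \eqn{Q^2 I}.
#' @export
kratky_transform <- function(curve) {
  stopifnot(inherits(curve, "scattering_curve"))
  scattering_curve(curve$q, curve$q^2 * curve$intensity,
                   sigma = if (!is.null(curve$sigma)) curve$q^2 * curve$sigma,
                   condition = curve$condition, position = curve$position)
}

#' Subtract a reference curve measured on the identical Q grid
#'
#' Positional residual scattering: the reference (for instance the bottom
#' part of the capillary) is subtracted point by point. The grids must match
#' exactly; no interpolation is attempted. Uncertainties combine in
#' quadrature when both curves carry them.
#'
#' @param curve,reference [scattering_curve()]s on the identical Q grid.
#' @return A [scattering_curve()] of differences.
#' @export
subtract_reference <- function(curve, reference) {
  stopifnot(inherits(curve, "scattering_curve"),
            inherits(reference, "scattering_curve"))
  if (length(curve$q) != length(reference$q) ||
      !isTRUE(all.equal(curve$q, reference$q, tolerance = 0)))
    stop("Q grids differ; subtract_reference requires an exact grid match")
  sigma <- NULL
  if (!is.null(curve$sigma) && !is.null(reference$sigma))
    sigma <- sqrt(curve$sigma^2 + reference$sigma^2)
  scattering_curve(curve$q, curve$intensity - reference$intensity,
                   sigma = sigma, condition = curve$condition,
                   position = curve$position)
}

#' Local power-law exponent of a scattering curve
#'
#' Least-squares slope of log I versus log Q inside a Q window, reported as
#' the positive exponent p of \eqn{I \propto Q^{-p}}. An exponent near 2
#' indicates thin plate-like scatterers.
#'
#' @param curve A [scattering_curve()] with positive intensities inside the
#'   window.
#' @param qmin,qmax Window limits (nm^-1), inclusive.
#' @return A list with `exponent`, `stderr`, `n`, and the window.
#' @export
local_power_law_slope <- function(curve, qmin, qmax) {
  stopifnot(inherits(curve, "scattering_curve"), qmin < qmax)
  sel <- curve$q >= qmin & curve$q <= qmax
  if (sum(sel) < 10L)
    stop("need at least 10 points inside [qmin, qmax]")
  if (any(curve$intensity[sel] <= 0))
    stop("intensities inside the window must be > 0")
  fit <- stats::lm(y ~ x, data = data.frame(x = log(curve$q[sel]),
                                            y = log(curve$intensity[sel])))
  # summary warns on an exactly collinear (pure power-law) fit; harmless here
  cf <- suppressWarnings(summary(fit)$coefficients)
  list(exponent = -unname(cf["x", "Estimate"]),
       stderr = unname(cf["x", "Std. Error"]),
       n = sum(sel), qmin = qmin, qmax = qmax)
}

#' Mean and standard error of parameter estimates
#'
#' Arithmetic mean with SEM = sample SD (n - 1 denominator) / sqrt(n), the
#' convention used for position-averaged fit parameters such as the average
#' lamellar radius of gyration across capillary positions.
#'
#' @param values Numeric vector, n >= 2, all finite.
#' @param digits Optional decimals for the rounded report.
#' @return List of class `sem_summary` with `mean`, `sem`, `n`, and (when
#'   `digits` is given) `mean_rounded`, `sem_rounded`.
#' @export
#' @examples
#' average_with_sem(c(6.48, 6.56, 6.78), digits = 2)  # 6.61 +/- 0.09
average_with_sem <- function(values, digits = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L || any(!is.finite(values)))
    stop("need at least 2 finite values")
  m <- mean(values)
  sem <- stats::sd(values) / sqrt(length(values))
  out <- list(mean = m, sem = sem, n = length(values))
  if (!is.null(digits)) {
    out$mean_rounded <- round(m, digits)
    out$sem_rounded <- round(sem, digits)
  }
  structure(out, class = "sem_summary")
}

#' @export
print.sem_summary <- function(x, ...) {
  cat(sprintf("%g +/- %g (n = %d)\n", x$mean, x$sem, x$n))
  invisible(x)
}
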