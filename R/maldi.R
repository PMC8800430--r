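#' Convert a molecular weight to a degree of polymerization
#'
#' \eqn{DP = (MW - adduct\_mass)/unit\_mass}. The default residue mass is
#' the average anhydroglucose mass 162.14 Da; the default adduct offset of
#' 41.0 Da (water 18.0 + Na 23.0) corresponds to sodiated oligosaccharide
#' ions, the usual MALDI species for cellodextrins.
#'
#' @param mw Molecular weight(s) in Da, > `adduct_mass`.
#' @param adduct_mass Adduct mass offset in Da (default 41.0).
#' @param unit_mass Repeat-unit (anhydroglucose) mass in Da (default 162.14).
#' @return Degree(s) of polymerization.
#' @export
#' @examples
#' mw_to_dp(1160)  # 6.90
#' mw_to_dp(1072)  # 6.36
mw_to_dp <- function(mw, adduct_mass = 41.0, unit_mass = 162.14) {
  if (any(mw <= adduct_mass)) stop("mw must exceed the adduct mass")
  (mw - adduct_mass) / unit_mass
}

#' Convert a degree of polymerization to a molecular weight
#'
#' Inverse of [mw_to_dp()]: \eqn{MW = unit\_mass \cdot DP + adduct\_mass}.
#'
#' @param dp Degree(s) of polymerization, > 0.
#' @inheritParams mw_to_dp
#' @return Molecular weight(s) in Da.
#' @export
dp_to_mw <- function(dp, adduct_mass = 41.0, unit_mass = 162.14) {
  if (any(dp <= 0)) stop("dp must be > 0")
  unit_mass * dp + adduct_mass
}

#' Pick the cellodextrin peak series from a mass spectrum
#'
#' Local maxima above a robust noise floor (median + 5 x MAD of the whole
#' spectrum) are matched to the mass comb
#' \eqn{m_n = unit\_mass \cdot n + adduct\_mass}; the returned series is the
#' longest consecutive run of matched integer degrees of polymerization.
#' Matching is invariant to uniform intensity scaling.
#'
#' @param spectrum A [mass_spectrum()].
#' @inheritParams mw_to_dp
#' @param match_tol Matching tolerance in Da, in (0, unit_mass/4); default 8.
#' @return An object of class `dp_series`: a data frame with columns `n`
#'   (DP), `mz_obs`, `height`, plus attributes `adduct_mass`, `unit_mass`
#'   and `reliable` (FALSE when fewer than 3 consecutive peaks were found).
#' @export
pick_series_peaks <- function(spectrum, adduct_mass = 41.0,
                              unit_mass = 162.14, match_tol = 8) {
  stopifnot(inherits(spectrum, "mass_spectrum"),
            match_tol > 0, match_tol < unit_mass / 4)
  y <- spectrum$intensity
  floor_level <- stats::median(y) + 5 * stats::mad(y)
  # local maxima (strictly above both neighbours) above the noise floor
  i <- which(diff(sign(diff(y))) < 0) + 1L
  i <- i[y[i] > floor_level]
  empty <- function(reliable) {
    out <- data.frame(n = integer(), mz_obs = numeric(), height = numeric())
    structure(out, class = c("dp_series", "data.frame"),
              adduct_mass = adduct_mass, unit_mass = unit_mass,
              reliable = reliable)
  }
  if (!length(i)) return(empty(FALSE))
  mz <- spectrum$mz[i]; h <- y[i]
  n_near <- round((mz - adduct_mass) / unit_mass)
  dev <- abs(mz - (unit_mass * n_near + adduct_mass))
  ok <- dev <= match_tol & n_near >= 1
  if (!any(ok)) return(empty(FALSE))
  d <- data.frame(n = n_near[ok], mz_obs = mz[ok], height = h[ok],
                  dev = dev[ok])
  # one observed peak per n: keep the closest to the comb position
  d <- d[order(d$n, d$dev), ]
  d <- d[!duplicated(d$n), ]
  # longest consecutive run of n
  runs <- split(d, cumsum(c(1, diff(d$n) != 1)))
  best <- runs[[which.max(vapply(runs, nrow, integer(1)))]]
  best$dev <- NULL
  rownames(best) <- NULL
  reliable <- nrow(best) >= 3L
  if (!reliable) warning("fewer than 3 consecutive series peaks: unreliable")
  structure(best, class = c("dp_series", "data.frame"),
            adduct_mass = adduct_mass, unit_mass = unit_mass,
            reliable = reliable)
}

#' Fit a Gaussian envelope through series peak tops
#'
#' Least-squares Gaussian in m/z through the (mz, height) peak tops of a
#' cellodextrin series. The fitted center is the mean molecular weight; the
#' mean degree of polymerization follows from the adduct relation
#' [mw_to_dp()]. The envelope is fitted in m/z, not in DP index, because
#' mean molecular weights are the primary report quantity.
#'
#' @param series A `dp_series` from [pick_series_peaks()] with >= 4 entries
#'   of positive height.
#' @return A list of class `dp_summary` with `mean_mw` (Da), `mean_dp`,
#'   `dp_min`, `dp_max`, `envelope_sigma` (Da), `envelope_height`, and
#'   `converged`.
#' @export
fit_gaussian_envelope <- function(series) {
  stopifnot(inherits(series, "dp_series"))
  if (nrow(series) < 4L)
    stop("need at least 4 series peaks to fit an envelope")
  if (any(series$height <= 0)) stop("peak heights must be positive")
  mz <- series$mz_obs; h <- series$height
  unit <- attr(series, "unit_mass"); adduct <- attr(series, "adduct_mass")
  start <- c(amp = max(h), center = sum(mz * h) / sum(h),
             sigma = max(stats::sd(mz) / 2, unit / 2))
  fit <- minpack.lm::nls.lm(
    par = start,
    lower = c(amp = 0, center = min(mz) - unit, sigma = unit / 10),
    upper = c(amp = Inf, center = max(mz) + unit, sigma = diff(range(mz)) * 2),
    fn = function(p) h - p[["amp"]] *
      exp(-(mz - p[["center"]])^2 / (2 * p[["sigma"]]^2)),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!(fit$info %in% 1:4))
    stop("envelope fit did not converge (nls.lm info = ", fit$info, ": ",
         fit$message, ")")
  mean_mw <- fit$par[["center"]]
  structure(list(mean_mw = mean_mw,
                 mean_dp = mw_to_dp(mean_mw, adduct, unit),
                 dp_min = min(series$n), dp_max = max(series$n),
                 envelope_sigma = fit$par[["sigma"]],
                 envelope_height = fit$par[["amp"]],
                 converged = TRUE),
            class = "dp_summary")
}

#' @export
print.dp_summary <- function(x, ...) {
  cat(sprintf("mean MW %.0f Da (mean DP = %.2f), DP range %d-%d, envelope sigma %.0f Da\n",
              x$mean_mw, x$mean_dp, x$dp_min, x$dp_max, x$envelope_sigma))
  invisible(x)
}
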