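#' Instrument geometry for angle conversions
#'
#' @param wavelength X-ray wavelength in Angstrom (default 0.92).
#' @param camera_length Sample-detector distance in mm (metadata only; not
#'   used in any computation).
#' @return An object of class `instrument_geometry`.
#' @export
instrument_geometry <- function(wavelength = 0.92, camera_length = NA_real_) {
  stopifnot(is.numeric(wavelength), length(wavelength) == 1L, wavelength > 0)
  structure(list(wavelength = wavelength, camera_length = camera_length),
            class = "instrument_geometry")
}

#' Convert scattering vector to lattice spacing
#'
#' \eqn{d = 2\pi/Q}, with Q in nm^-1 and d returned in Angstrom (x 10).
#'
#' @param q Scattering vector(s), nm^-1, > 0.
#' @return Lattice spacing(s) in Angstrom.
#' @export
#' @examples
#' q_to_d(8.69)   # 7.23 A, the cellulose II 1-10 reflection
#' q_to_d(15.6)   # 4.03 A, the 020 reflection
q_to_d <- function(q) {
  if (any(!is.finite(q)) || any(q <= 0)) stop("q must be finite and > 0")
  2 * pi / q * 10
}

#' Convert lattice spacing to scattering vector
#'
#' Inverse of [q_to_d()]: \eqn{Q = 2\pi/d} with d in Angstrom, Q in nm^-1.
#'
#' @param d Lattice spacing(s) in Angstrom, > 0.
#' @return Scattering vector(s) in nm^-1.
#' @export
d_to_q <- function(d) {
  if (any(!is.finite(d)) || any(d <= 0)) stop("d must be finite and > 0")
  2 * pi / (d / 10)
}

#' Convert scattering vector to scattering angle
#'
#' \eqn{2\theta = 2\arcsin(Q\lambda/4\pi)} in degrees, from
#' \eqn{Q = 4\pi\sin\theta/\lambda} (Q in nm^-1, wavelength in Angstrom).
#'
#' @param q Scattering vector(s), nm^-1.
#' @param geometry An [instrument_geometry()].
#' @return Scattering angle(s) 2-theta in degrees.
#' @export
q_to_two_theta <- function(q, geometry = instrument_geometry()) {
  stopifnot(inherits(geometry, "instrument_geometry"))
  arg <- (q / 10) * geometry$wavelength / (4 * pi)  # q to A^-1
  if (any(arg > 1)) stop("q lambda / 4 pi exceeds 1: angle undefined")
  2 * asin(arg) * 180 / pi
}

#' Convert a FWHM in Q to a FWHM in 2-theta
#'
#' Endpoint conversion: the half-maximum Q positions
#' \eqn{Q_c \pm FWHM_Q/2} are converted individually and differenced, so the
#' nonlinearity of the arcsine is respected.
#'
#' @param center_q Peak center, nm^-1.
#' @param fwhm_q Full width at half maximum in Q, nm^-1.
#' @inheritParams q_to_two_theta
#' @return FWHM in degrees 2-theta.
#' @export
fwhm_q_to_fwhm_two_theta <- function(center_q, fwhm_q,
                                     geometry = instrument_geometry()) {
  q_to_two_theta(center_q + fwhm_q / 2, geometry) -
    q_to_two_theta(center_q - fwhm_q / 2, geometry)
}

#' Estimate the smooth solvent background under diffraction peaks
#'
#' Fits a low-order polynomial (degree <= 4) to the points outside all peak
#' windows, on the premise that solvent (water) scattering is smooth and
#' forms no peak. The degree is selected by BIC on the out-of-window points,
#' so an unnecessarily high degree never over-fits noise (important where a
#' peak window touches the edge of the measured range and the polynomial
#' must extrapolate). When the out-of-window data are monotone, monotone
#' candidate fits are preferred (degree 1 always qualifies).
#'
#' @param profile A [scattering_curve()].
#' @param peak_windows List of numeric length-2 vectors `(qlo, qhi)` marking
#'   peak regions to exclude from the background fit.
#' @param degree Maximum polynomial degree (default 4).
#' @return A [scattering_curve()] with the background evaluated on the full
#'   grid.
#' @export
estimate_smooth_background <- function(profile, peak_windows, degree = 4L) {
  stopifnot(inherits(profile, "scattering_curve"), degree >= 1L, degree <= 4L)
  q <- profile$q
  inside <- rep(FALSE, length(q))
  for (w in peak_windows) {
    if (w[1] < min(q) - 1e-9 || w[2] > max(q) + 1e-9)
      stop("peak window outside the profile's Q range")
    inside <- inside | (q >= w[1] & q <= w[2])
  }
  if (mean(!inside) < 0.3)
    stop("fewer than 30% of points outside peak windows: not enough support")
  qs <- q[!inside]; ys <- profile$intensity[!inside]
  n <- length(qs)
  data_monotone <- all(diff(ys) >= 0) || all(diff(ys) <= 0)
  cand <- lapply(seq_len(degree), function(deg) {
    fit <- stats::lm(ys ~ stats::poly(qs, deg, raw = TRUE))
    bg <- drop(cbind(1, outer(q, seq_len(deg), `^`)) %*% stats::coef(fit))
    rss <- sum(stats::residuals(fit)^2)
    list(bg = bg,
         bic = n * log(max(rss, .Machine$double.xmin) / n) +
           (deg + 2) * log(n),
         monotone = all(diff(bg) >= 0) || all(diff(bg) <= 0))
  })
  ok <- if (data_monotone) Filter(function(cc) cc$monotone, cand) else cand
  if (!length(ok)) ok <- cand
  bg <- ok[[which.min(vapply(ok, `[[`, numeric(1), "bic"))]]$bg
  scattering_curve(q, bg, condition = profile$condition,
                   position = profile$position)
}

#' Fit Gaussian peaks over a background, window by window
#'
#' For each window a single Gaussian is fitted by Levenberg-Marquardt least
#' squares to the background-subtracted profile. The integrated area is
#' reported as amplitude x FWHM x sqrt(pi / (4 ln 2)). Windows where the
#' fitted amplitude is not positive are reported with area 0 and flagged
#' `absent`. Positions are also given in degrees 2-theta via the supplied
#' geometry.
#'
#' @param profile A [scattering_curve()].
#' @param background A [scattering_curve()] on the identical grid (e.g. from
#'   [estimate_smooth_background()]).
#' @param windows List of numeric length-2 vectors `(qlo, qhi)`.
#' @param geometry An [instrument_geometry()] for the 2-theta columns.
#' @return A data frame of class `peak_fits` with one row per window:
#'   `center_q`, `fwhm_q`, `area`, their standard errors, `center_2theta`,
#'   `fwhm_2theta`, and `absent`.
#' @export
fit_peaks <- function(profile, background, windows,
                      geometry = instrument_geometry()) {
  stopifnot(inherits(profile, "scattering_curve"),
            inherits(background, "scattering_curve"))
  if (!isTRUE(all.equal(profile$q, background$q, tolerance = 0)))
    stop("background must be on the identical Q grid")
  excess_all <- profile$intensity - background$intensity
  rows <- lapply(windows, function(w) {
    sel <- profile$q >= w[1] & profile$q <= w[2]
    q <- profile$q[sel]; y <- excess_all[sel]
    if (sum(sel) < 8L) stop("window [", w[1], ", ", w[2], "] has < 8 points")
    a0 <- max(y); c0 <- q[which.max(y)]
    s0 <- max(diff(range(q)) / 10, 1e-3)
    absent <- FALSE
    if (a0 <= 0) {
      absent <- TRUE
      est <- c(amp = 0, center = mean(q), sigma = s0)
      se <- c(amp = NA_real_, center = NA_real_, sigma = NA_real_)
    } else {
      fit <- minpack.lm::nls.lm(
        par = c(amp = a0, center = c0, sigma = s0),
        lower = c(amp = 0, center = w[1], sigma = 1e-4),
        upper = c(amp = Inf, center = w[2], sigma = diff(range(q))),
        fn = function(p) y - p[["amp"]] *
          exp(-(q - p[["center"]])^2 / (2 * p[["sigma"]]^2)),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      est <- fit$par
      se <- tryCatch({
        cf <- summary(fit)$coefficients
        stats::setNames(cf[, "Std. Error"], rownames(cf))
      }, error = function(e)
        c(amp = NA_real_, center = NA_real_, sigma = NA_real_))
      if (est[["amp"]] <= 0) absent <- TRUE
    }
    fwhm <- 2 * sqrt(2 * log(2)) * est[["sigma"]]
    area_per_amp_fwhm <- sqrt(pi / (4 * log(2)))
    area <- if (absent) 0 else est[["amp"]] * fwhm * area_per_amp_fwhm
    fwhm_se <- 2 * sqrt(2 * log(2)) * se[["sigma"]]
    # first-order error propagation for the area product
    area_se <- if (absent || anyNA(se)) NA_real_ else
      area * sqrt((se[["amp"]] / est[["amp"]])^2 +
                  (se[["sigma"]] / est[["sigma"]])^2)
    data.frame(center_q = est[["center"]], fwhm_q = fwhm, area = area,
               center_q_se = se[["center"]], fwhm_q_se = fwhm_se,
               area_se = area_se,
               center_2theta = q_to_two_theta(est[["center"]], geometry),
               fwhm_2theta = fwhm_q_to_fwhm_two_theta(est[["center"]], fwhm,
                                                      geometry),
               absent = absent)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("peak_fits", "data.frame")
  out
}

#' Reference d-spacings of cellulose II
#'
#' The 1-10, 110 and 020 reflections at d = 7.23, 4.45 and 4.03 Angstrom
#' (Q = 8.69, 14.1 and 15.6 nm^-1).
#'
#' @return Named numeric vector of d-spacings in Angstrom.
#' @export
cellulose_ii_dspacings <- function() {
  c("1-10" = 7.23, "110" = 4.45, "020" = 4.03)
}

#' Default peak windows around the cellulose II reflections
#'
#' Windows of +/- `half_width` nm^-1 around the 1-10, 110 and 020 positions,
#' optionally clamped to a profile's Q range.
#'
#' @param half_width Half window width in nm^-1 (default 0.8).
#' @param qlim Optional length-2 vector (or [scattering_curve()]) to clamp
#'   the windows to.
#' @return Named list of length-2 numeric windows.
#' @export
cellulose_peak_windows <- function(half_width = 0.8, qlim = NULL) {
  centers <- d_to_q(cellulose_ii_dspacings())
  if (inherits(qlim, "scattering_curve")) qlim <- range(qlim$q)
  lapply(as.list(centers), function(cq) {
    w <- c(cq - half_width, cq + half_width)
    if (!is.null(qlim)) w <- c(max(w[1], qlim[1]), min(w[2], qlim[2]))
    w
  })
}

#' Assign diffraction peaks to cellulose II reflections
#'
#' Each peak's observed d-spacing (from [q_to_d()]) is matched to the
#' nearest reference plane within a relative tolerance; matching is
#' one-to-one (closest peak wins; ties broken toward the lower reference
#' d). Unmatched peaks are labeled `"unassigned"`.
#'
#' @param peaks A `peak_fits` data frame from [fit_peaks()].
#' @param reference Named vector of reference d-spacings in Angstrom
#'   (default [cellulose_ii_dspacings()]).
#' @param tolerance Relative tolerance, in (0, 0.1]; default 0.02.
#' @return A data frame with columns `center_q`, `d_obs`, `plane`, `d_ref`.
#' @export
assign_reflections <- function(peaks, reference = cellulose_ii_dspacings(),
                               tolerance = 0.02) {
  stopifnot(tolerance > 0, tolerance <= 0.1)
  if (nrow(peaks) == 0L)
    return(data.frame(center_q = numeric(), d_obs = numeric(),
                      plane = character(), d_ref = numeric()))
  d_obs <- q_to_d(peaks$center_q)
  plane <- rep("unassigned", length(d_obs))
  d_ref <- rep(NA_real_, length(d_obs))
  # candidate (peak, plane) pairs within tolerance, best matches first
  cand <- expand.grid(pk = seq_along(d_obs), pl = seq_along(reference))
  cand$rel <- abs(d_obs[cand$pk] - reference[cand$pl]) / reference[cand$pl]
  cand <- cand[cand$rel <= tolerance, ]
  cand <- cand[order(cand$rel, reference[cand$pl]), ]
  used_pl <- logical(length(reference))
  for (i in seq_len(nrow(cand))) {
    pk <- cand$pk[i]; pl <- cand$pl[i]
    if (plane[pk] != "unassigned" || used_pl[pl]) next
    plane[pk] <- names(reference)[pl]
    d_ref[pk] <- reference[[pl]]
    used_pl[pl] <- TRUE
  }
  data.frame(center_q = peaks$center_q, d_obs = d_obs, plane = plane,
             d_ref = d_ref)
}

#' Average a quantity over the three capillary positions
#'
#' Arithmetic mean over the upper, middle and bottom measurement positions,
#' with a report value rounded to a stated precision (peak areas and FWHMs
#' are conventionally tabulated per position with a trailing average
#' column).
#'
#' @param values Named numeric vector or list with exactly the elements
#'   `upper`, `middle`, `bottom`.
#' @param digits Decimals for the rounded report value (default: inferred
#'   from the printed precision of the inputs).
#' @return List with `mean` (full precision), `rounded`, and `digits`.
#' @export
#' @examples
#' summarize_positions(c(upper = 125, middle = 88.8, bottom = 93.9))$rounded
summarize_positions <- function(values, digits = NULL) {
  values <- unlist(values)
  need <- c("upper", "middle", "bottom")
  if (!all(need %in% names(values)))
    stop("values must carry exactly the positions upper, middle, bottom")
  values <- values[need]
  if (any(!is.finite(values))) stop("all three positions must be finite")
  if (is.null(digits)) {
    # infer decimals from the shortest printed representation of the inputs
    dec <- vapply(values, function(v) {
      s <- sub("0+$", "", sub(".*\\.", "", format(v, digits = 15)))
      if (grepl("\\.", format(v, digits = 15))) nchar(s) else 0L
    }, integer(1))
    digits <- min(dec)
  }
  m <- mean(values)
  list(mean = m, rounded = round(m, digits), digits = digits)
}
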