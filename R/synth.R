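#' Synthetic-data generator configuration
#'
#' A validated configuration for one of the four generators: SAXS curves
#' from the two-level unified model, WAXS profiles (smooth monotone water
#' background plus Gaussian crystalline peaks), MALDI cellodextrin peak
#' combs, and ribbon-network micrographs. Every generator is fully
#' determined by its seed and echoes machine-readable ground truth so that
#' downstream estimators can be scored.
#'
#' Grid specifications by kind:
#' \describe{
#'   \item{saxs}{`list(qmin, qmax, n, spacing = "log"|"linear")`, Q in nm^-1
#'     (defaults 0.07, 2.5, 200, log).}
#'   \item{waxs}{`list(qmin, qmax, n)` (defaults 5, 16, 550), linear.}
#'   \item{maldi}{`list(mz_min, mz_max, step)` in Da (defaults 400, 2100, 0.25).}
#'   \item{ribbon_image}{`list(size = c(nrow, ncol), pixel_size)` in px and
#'     um/px (defaults 512 x 512, 0.05).}
#' }
#'
#' Truth blocks by kind:
#' \describe{
#'   \item{saxs}{a [unified_params()] object.}
#'   \item{waxs}{`list(peaks = data.frame(center, fwhm, area),
#'     background = c(b0, b1, b2, ...))` polynomial coefficients in Q (must
#'     be monotone over the grid).}
#'   \item{maldi}{`list(mean_dp, dp_sigma, dp_range, adduct_mass, unit_mass,
#'     peak_sigma_mz, envelope_height)`.}
#'   \item{ribbon_image}{either `list(n_ribbons, width_mean, width_sd,
#'     length_range, orientation_range)` (widths drawn from the lognormal
#'     with the stated mean/SD in um) or `list(ribbons = data.frame(row,
#'     col, orientation, length_px, width_px))` for fully explicit layouts.}
#' }
#'
#' @param kind One of `"saxs"`, `"waxs"`, `"maldi"`, `"ribbon_image"`.
#' @param seed Integer RNG seed; identical configurations give bit-identical
#'   output.
#' @param noise Fractional noise level (>= 0). Multiplicative Gaussian for
#'   SAXS (constant fractional error, as in count-dominated synchrotron data
#'   at moderate intensity); additive Gaussian baseline noise for WAXS and
#'   MALDI; ignored for binary ribbon images.
#' @param grid Axis specification (see Details); `NULL` for defaults.
#' @param truth Generator-specific ground-truth block (see Details).
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(kind = c("saxs", "waxs", "maldi", "ribbon_image"),
                         seed = 1L, noise = 0, grid = NULL, truth = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(noise), length(noise) == 1L, noise >= 0)
  grid <- switch(kind,
    saxs = utils::modifyList(
      list(qmin = 0.07, qmax = 2.5, n = 200L, spacing = "log"),
      as.list(grid)),
    waxs = utils::modifyList(list(qmin = 5, qmax = 16, n = 550L),
                             as.list(grid)),
    maldi = utils::modifyList(list(mz_min = 400, mz_max = 2100, step = 0.25),
                              as.list(grid)),
    ribbon_image = utils::modifyList(
      list(size = c(512L, 512L), pixel_size = 0.05), as.list(grid)))
  if (kind == "ribbon_image") {
    if (any(grid$size < 64L)) stop("image dimensions must be >= 64 x 64 px")
    if (grid$pixel_size <= 0) stop("pixel_size must be > 0")
  } else {
    lo <- grid[[1L]]; hi <- grid[[2L]]
    if (!(lo > 0 && hi > lo)) stop("grid axis must be positive and increasing")
  }
  structure(list(kind = kind, seed = as.integer(seed), noise = noise,
                 grid = grid, truth = truth),
            class = "synth_config")
}

# run expr under a temporary RNG state so generators are seed-deterministic
# without clobbering the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

saxs_grid <- function(grid) {
  if (identical(grid$spacing, "log"))
    10^seq(log10(grid$qmin), log10(grid$qmax), length.out = grid$n)
  else seq(grid$qmin, grid$qmax, length.out = grid$n)
}

#' Generate a synthetic SAXS curve with known unified-model truth
#'
#' Evaluates the two-level unified model on the configured Q grid and
#' applies multiplicative Gaussian noise:
#' \eqn{I_k = I_{model}(Q_k)(1 + noise\,\epsilon_k)}. Points where the noisy
#' intensity would go negative are regenerated deterministically with
#' \eqn{\epsilon} truncated at \eqn{\pm 5} and flagged. Reported
#' uncertainties are \eqn{noise \cdot I_{model}} (omitted when noise = 0).
#'
#' @param config A [synth_config()] with `kind = "saxs"` and a
#'   [unified_params()] truth block.
#' @return A list with `curve` ([scattering_curve()]), `truth` (the exact
#'   parameters), `model_intensity`, `truncated` (indices where the noise
#'   deviate was truncated) and `config`.
#' @export
#' @examples
#' p <- unified_params(0.791, 3360, 0.619, 34.4, 2.78, 56.4, 1.32, 6.48, 2.71)
#' g <- generate_saxs_curve(synth_config("saxs", seed = 1, noise = 0.02, truth = p))
generate_saxs_curve <- function(config) {
  stopifnot(inherits(config, "synth_config"), config$kind == "saxs",
            inherits(config$truth, "unified_params"))
  q <- saxs_grid(config$grid)
  imod <- unified_model_intensity(config$truth, q)
  truncated <- integer(0)
  if (config$noise > 0) {
    eps <- with_seed(config$seed, stats::rnorm(length(q)))
    intensity <- imod * (1 + config$noise * eps)
    bad <- which(intensity <= 0)
    if (length(bad)) {
      truncated <- bad
      eps[bad] <- pmax(pmin(eps[bad], 5), -5)
      intensity <- imod * (1 + config$noise * eps)
      warning(length(bad), " points had noise deviates truncated at +/-5")
    }
    sigma <- config$noise * imod
  } else {
    intensity <- imod
    sigma <- NULL
  }
  list(curve = scattering_curve(q, intensity, sigma = sigma,
                                condition = "synthetic"),
       truth = config$truth, model_intensity = imod,
       truncated = truncated, config = config)
}

# Gaussian peak parameterized by integrated area and FWHM:
# amplitude = area / (FWHM * sqrt(pi / (4 log 2)))
gauss_peak <- function(q, center, fwhm, area) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  amp <- area / (fwhm * sqrt(pi / (4 * log(2))))
  amp * exp(-(q - center)^2 / (2 * s^2))
}

#' Generate a synthetic WAXS profile: smooth water background plus peaks
#'
#' The background is a low-order polynomial in Q (monotone over the grid,
#' emulating the smooth, peak-free rise of water scattering across
#' 5-16 nm^-1); crystalline peaks are Gaussians specified by (center, FWHM,
#' area). Additive Gaussian noise with SD = `noise` x mean clean intensity.
#' Peak pairs closer than 0.2 x the larger FWHM are still generated but
#' flagged unresolvable.
#'
#' @param config A [synth_config()] with `kind = "waxs"`.
#' @return A list with `profile` ([scattering_curve()]), `background`
#'   (numeric vector of the exact background), `truth` (the peak table),
#'   `unresolvable` (logical), and `config`.
#' @export
generate_waxs_profile <- function(config) {
  stopifnot(inherits(config, "synth_config"), config$kind == "waxs")
  truth <- config$truth
  if (is.null(truth$background)) stop("truth$background coefficients required")
  q <- seq(config$grid$qmin, config$grid$qmax, length.out = config$grid$n)
  bg <- drop(outer(q, seq_along(truth$background) - 1, `^`) %*%
               truth$background)
  if (min(diff(bg)) < -1e-9 && max(diff(bg)) > 1e-9)
    stop("truth background must be monotone over the grid")
  peaks <- truth$peaks
  total <- bg
  unresolvable <- FALSE
  if (!is.null(peaks) && nrow(peaks)) {
    for (i in seq_len(nrow(peaks)))
      total <- total + gauss_peak(q, peaks$center[i], peaks$fwhm[i],
                                  peaks$area[i])
    if (nrow(peaks) > 1L) {
      dc <- abs(diff(sort(peaks$center)))
      wmax <- max(peaks$fwhm)
      unresolvable <- any(dc < 0.2 * wmax)
      if (unresolvable) warning("peaks closer than 0.2 x FWHM: unresolvable")
    }
  }
  if (config$noise > 0) {
    sdev <- config$noise * mean(total)
    total <- total + with_seed(config$seed, stats::rnorm(length(q), sd = sdev))
  }
  list(profile = scattering_curve(q, total, condition = "synthetic"),
       background = bg, truth = peaks, unresolvable = unresolvable,
       config = config)
}

#' Generate a synthetic MALDI-ToF cellodextrin spectrum
#'
#' Peaks are placed at \eqn{m_n = unit\_mass \cdot n + adduct\_mass} for
#' integer degrees of polymerization n in `dp_range`; peak heights follow a
#' Gaussian envelope in n centered on `mean_dp`; each peak is rendered as a
#' narrow Gaussian in m/z. Baseline noise is one-sided additive
#' (`noise * envelope_height * |N(0,1)|`) so intensities stay non-negative.
#'
#' @param config A [synth_config()] with `kind = "maldi"`. Truth defaults:
#'   `mean_dp = 6.9`, `dp_sigma = 1.2`, `dp_range = c(4, 11)`,
#'   `adduct_mass = 41.0`, `unit_mass = 162.14`, `peak_sigma_mz = 2`,
#'   `envelope_height = 100`.
#' @return A list with `spectrum` ([mass_spectrum()]), `truth` (full
#'   parameter block plus the exact peak positions and heights), `config`.
#' @export
generate_maldi_spectrum <- function(config) {
  stopifnot(inherits(config, "synth_config"), config$kind == "maldi")
  tr <- utils::modifyList(
    list(mean_dp = 6.9, dp_sigma = 1.2, dp_range = c(4L, 11L),
         adduct_mass = 41.0, unit_mass = 162.14, peak_sigma_mz = 2,
         envelope_height = 100),
    as.list(config$truth))
  if (tr$dp_range[2] < tr$dp_range[1]) stop("empty DP range")
  if (tr$mean_dp <= 0 || tr$dp_sigma <= 0)
    stop("mean DP and spread must be positive")
  n <- seq.int(tr$dp_range[1], tr$dp_range[2])
  pos <- tr$unit_mass * n + tr$adduct_mass
  height <- tr$envelope_height * exp(-(n - tr$mean_dp)^2 / (2 * tr$dp_sigma^2))
  mz <- seq(config$grid$mz_min, config$grid$mz_max, by = config$grid$step)
  intensity <- rep(0, length(mz))
  for (i in seq_along(n))
    intensity <- intensity +
      height[i] * exp(-(mz - pos[i])^2 / (2 * tr$peak_sigma_mz^2))
  if (config$noise > 0)
    intensity <- intensity + config$noise * tr$envelope_height *
      abs(with_seed(config$seed, stats::rnorm(length(mz))))
  tr$dp <- n; tr$peak_mz <- pos; tr$peak_height <- height
  list(spectrum = mass_spectrum(mz, intensity, condition = "synthetic"),
       truth = tr, config = config)
}

# lognormal meanlog/sdlog from arithmetic mean m and SD s
lognormal_from_moments <- function(m, s) {
  sdlog2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Generate a synthetic ribbon-network micrograph
#'
#' Straight ribbons of constant per-ribbon width are rasterized onto an
#' 8-bit grayscale canvas (foreground 200/255, background 20/255, optional
#' light Gaussian blur). Widths are drawn from a lognormal parameterized by
#' its arithmetic mean and SD in micrometres; the exact drawn widths are
#' echoed as ground truth. A fully explicit `ribbons` data frame (columns
#' `row`, `col`, `orientation` (radians), `length_px`, `width_px`) may be
#' given instead, in which case any requested width below 3 px is rejected
#' as unmeasurable.
#'
#' @param config A [synth_config()] with `kind = "ribbon_image"`. Truth
#'   defaults: `n_ribbons = 200`, `width_mean = 0.254`, `width_sd = 0.128`
#'   (um), `length_range = c(3, 8)` (um), `orientation_range = c(0, pi)`.
#' @param blur_sigma Optional Gaussian blur SD in px (0 = binary-like).
#' @return A list with `image` ([micrograph()]), `truth_widths_um` (drawn
#'   widths), `ribbons` (the full layout table), `config`.
#' @export
generate_ribbon_image <- function(config, blur_sigma = 0) {
  stopifnot(inherits(config, "synth_config"), config$kind == "ribbon_image")
  sz <- config$grid$size
  px <- config$grid$pixel_size
  tr <- utils::modifyList(
    list(n_ribbons = 200L, width_mean = 0.254, width_sd = 0.128,
         length_range = c(3, 8), orientation_range = c(0, pi)),
    as.list(config$truth))
  if (!is.null(tr$ribbons)) {
    rb <- tr$ribbons
    if (any(rb$width_px < 3))
      stop("requested ribbon width below 3 px is unmeasurable")
  } else {
    ln <- lognormal_from_moments(tr$width_mean, tr$width_sd)
    rb <- with_seed(config$seed, {
      width_um <- stats::rlnorm(tr$n_ribbons, ln$meanlog, ln$sdlog)
      data.frame(
        row = stats::runif(tr$n_ribbons, 1, sz[1]),
        col = stats::runif(tr$n_ribbons, 1, sz[2]),
        orientation = stats::runif(tr$n_ribbons, tr$orientation_range[1],
                                   tr$orientation_range[2]),
        length_px = stats::runif(tr$n_ribbons, tr$length_range[1],
                                 tr$length_range[2]) / px,
        width_px = width_um / px)
    })
  }
  img <- matrix(20 / 255, sz[1], sz[2])
  fg <- 200 / 255
  for (i in seq_len(nrow(rb))) {
    o <- rb$orientation[i]; ux <- cos(o); uy <- sin(o)
    half_l <- rb$length_px[i] / 2; half_w <- rb$width_px[i] / 2
    pad <- half_l + half_w + 1
    r0 <- max(1L, floor(rb$row[i] - pad)); r1 <- min(sz[1], ceiling(rb$row[i] + pad))
    c0 <- max(1L, floor(rb$col[i] - pad)); c1 <- min(sz[2], ceiling(rb$col[i] + pad))
    rr <- r0:r1; cc <- c0:c1
    dy <- outer(rr - rb$row[i], rep(1, length(cc)))
    dx <- outer(rep(1, length(rr)), cc - rb$col[i])
    along <- dx * ux + dy * uy
    perp <- -dx * uy + dy * ux
    hit <- abs(perp) <= half_w & abs(along) <= half_l
    block <- img[rr, cc, drop = FALSE]
    block[hit] <- fg
    img[rr, cc] <- block
  }
  if (blur_sigma > 0)
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = blur_sigma))
  list(image = micrograph(img, px, condition = "synthetic"),
       truth_widths_um = rb$width_px * px, ribbons = rb, config = config)
}
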