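#' One-dimensional scattering curve
#'
#' Container for a radially integrated X-ray scattering profile \eqn{I(Q)},
#' shared by the SAXS and WAXS stages. The scattering vector is
#' \eqn{Q = 4\pi \sin\theta / \lambda} in nm\eqn{^{-1}}, where \eqn{2\theta}
#' is the scattering angle and \eqn{\lambda} the wavelength.
#'
#' @param q Numeric vector of scattering-vector values (nm^-1), strictly
#'   increasing and positive, length >= 10.
#' @param intensity Numeric vector of intensities (arbitrary units), same
#'   length as `q`.
#' @param sigma Optional numeric vector of 1-sigma intensity uncertainties;
#'   strictly positive when supplied.
#' @param condition Free-text condition label (e.g. `"space"`, `"ground"`).
#' @param position Optional capillary position, one of `"upper"`, `"middle"`,
#'   `"bottom"` (measured 10/14/18 mm from the capillary top).
#'
#' @return An object of class `scattering_curve`: a list with elements
#'   `q`, `intensity`, `sigma`, `condition`, `position`.
#' @export
#' @examples
#' sc <- scattering_curve(seq(0.1, 2, length.out = 50), rexp(50) + 1)
scattering_curve <- function(q, intensity, sigma = NULL,
                             condition = NA_character_, position = NULL) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) < 10L)
    stop("scattering curve needs at least 10 points")
  if (length(intensity) != length(q))
    stop("q and intensity lengths differ")
  if (any(!is.finite(q)) || any(q <= 0))
    stop("q must be finite and > 0")
  if (any(diff(q) <= 0))
    stop("q must be strictly increasing")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q))
      stop("sigma length differs from q")
    if (any(!is.finite(sigma)) || any(sigma <= 0))
      stop("sigma must be finite and strictly positive")
  }
  if (!is.null(position)) {
    position <- match.arg(position, c("upper", "middle", "bottom"))
  }
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 condition = condition, position = position),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("scattering_curve: %d points, Q in [%.4g, %.4g] nm^-1\n",
              length(x$q), min(x$q), max(x$q)))
  if (!is.na(x$condition)) cat("  condition:", x$condition, "\n")
  if (!is.null(x$position)) cat("  position:", x$position,
                                sprintf("(%d mm)", position_offset_mm(x$position)), "\n")
  if (!is.null(x$sigma)) cat("  1-sigma uncertainties present\n")
  invisible(x)
}

#' @export
length.scattering_curve <- function(x) length(x$q)

#' @export
as.data.frame.scattering_curve <- function(x, ...) {
  d <- data.frame(q = x$q, intensity = x$intensity)
  if (!is.null(x$sigma)) d$sigma <- x$sigma
  d
}

# capillary offsets, mm from the top
position_offset_mm <- function(position) {
  c(upper = 10, middle = 14, bottom = 18)[[position]]
}

#' MALDI-ToF mass spectrum
#'
#' @param mz Numeric m/z axis (Da), strictly increasing.
#' @param intensity Non-negative intensities, same length.
#' @param condition Free-text condition label.
#'
#' @return An object of class `mass_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity, condition = NA_character_) {
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity lengths differ")
  if (any(!is.finite(mz)) || any(diff(mz) <= 0))
    stop("mz must be finite and strictly increasing")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensity must be finite and >= 0")
  structure(list(mz = mz, intensity = intensity, condition = condition),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("mass_spectrum: %d points, m/z in [%.1f, %.1f] Da\n",
              length(x$mz), min(x$mz), max(x$mz)))
  invisible(x)
}

#' Grayscale micrograph with physical pixel size
#'
#' @param pixels Numeric matrix in `[0, 1]` (or integer 0-255, rescaled),
#'   at least 64 x 64.
#' @param pixel_size Pixel size in micrometres per pixel, > 0.
#' @param condition Free-text condition label.
#'
#' @return An object of class `micrograph`.
#' @export
micrograph <- function(pixels, pixel_size, condition = NA_character_) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (any(dim(pixels) < 64L)) stop("micrograph must be at least 64 x 64 px")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number (um/px)")
  pixels <- pixels * 1.0
  if (max(pixels) > 1) pixels <- pixels / 255
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("pixel values must lie in [0, 1] or 0..255")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 condition = condition),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("micrograph: %d x %d px at %.4g um/px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size))
  invisible(x)
}

#' Read a scattering curve from delimited text
#'
#' Accepts 2-column (Q, I) or 3-column (Q, I, sigma) whitespace- or
#' comma-separated files; lines starting with `#` are comments. Q is assumed
#' to be in nm^-1 unless `q_unit = "A^-1"`, in which case it is converted
#' (x 10).
#'
#' @param path File path.
#' @param q_unit `"nm^-1"` (default) or `"A^-1"`.
#' @inheritParams scattering_curve
#' @return A [scattering_curve()].
#' @export
read_scattering_curve <- function(path, q_unit = c("nm^-1", "A^-1"),
                                  condition = NA_character_, position = NULL) {
  q_unit <- match.arg(q_unit)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  sep <- if (any(grepl(",", lines))) "," else ""
  d <- utils::read.table(text = lines, sep = sep, header = FALSE)
  if (ncol(d) < 2L) stop("expected at least two columns (Q, I)")
  q <- d[[1L]]
  if (q_unit == "A^-1") q <- q * 10
  scattering_curve(q, d[[2L]],
                   sigma = if (ncol(d) >= 3L) d[[3L]] else NULL,
                   condition = condition, position = position)
}

#' Write a scattering curve (or mass spectrum) as tab-separated text
#'
#' A `#`-prefixed comment header can carry arbitrary metadata such as the
#' generator's ground-truth block.
#'
#' @param x A [scattering_curve()] or [mass_spectrum()].
#' @param path Output path.
#' @param header Optional character vector written as `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_scattering_curve <- function(x, path, header = character()) {
  d <- as.data.frame(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header))
    writeLines(paste0("# ", header), con)
  writeLines(paste("#", paste(names(d), collapse = "\t")), con)
  utils::write.table(format(d, digits = 15, trim = TRUE), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.mass_spectrum <- function(x, ...) {
  data.frame(mz = x$mz, intensity = x$intensity)
}

#' Read a two-column mass spectrum (m/z, intensity)
#'
#' @inheritParams read_scattering_curve
#' @return A [mass_spectrum()].
#' @export
read_mass_spectrum <- function(path, condition = NA_character_) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  sep <- if (any(grepl(",", lines))) "," else ""
  d <- utils::read.table(text = lines, sep = sep, header = FALSE)
  if (ncol(d) < 2L) stop("expected two columns (m/z, intensity)")
  mass_spectrum(d[[1L]], d[[2L]], condition = condition)
}

#' Read an 8-bit grayscale micrograph (PNG or TIFF)
#'
#' @param path Image path ending in `.png`, `.tif` or `.tiff`.
#' @param pixel_size Micrometres per pixel.
#' @param condition Free-text condition label.
#' @return A [micrograph()].
#' @export
read_micrograph <- function(path, pixel_size, condition = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel of RGB(A)
  micrograph(img, pixel_size, condition = condition)
}

#' Write a micrograph as 8-bit grayscale PNG
#'
#' @param x A [micrograph()].
#' @param path Output path (`.png`).
#' @param sidecar If `TRUE` (default), also write `<path>.meta.txt` with the
#'   pixel size so the image can be re-read without external bookkeeping.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(x, path, sidecar = TRUE) {
  png::writePNG(x$pixels, path)
  if (sidecar)
    writeLines(c(sprintf("pixel_size_um: %.10g", x$pixel_size),
                 sprintf("condition: %s", x$condition)),
               paste0(path, ".meta.txt"))
  invisible(path)
}
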