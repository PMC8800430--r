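#' Segment fibers from a grayscale micrograph
#'
#' Thresholds the image (Otsu's method by default, or a fixed threshold),
#' removes connected foreground objects smaller than `min_object` pixels
#' and fills enclosed background holes smaller than `max_hole` pixels.
#'
#' @param image A [micrograph()].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Threshold in `[0, 1]` when `method = "fixed"`.
#' @param invert Set `TRUE` for dark-foreground images; the mask is then
#'   identical to the one obtained from the contrast-inverted image.
#' @param min_object Minimum object size kept, px (default 20).
#' @param max_hole Maximum hole size filled, px (default 20).
#' @return A logical matrix (`TRUE` = fiber). An empty mask (with a
#'   warning) results when no foreground is found; downstream measurement
#'   refuses empty masks.
#' @export
segment_fibers <- function(image, method = c("otsu", "fixed"),
                           threshold = NULL, invert = FALSE,
                           min_object = 20L, max_hole = 20L) {
  stopifnot(inherits(image, "micrograph"))
  method <- match.arg(method)
  x <- image$pixels
  if (invert) x <- 1 - x
  if (diff(range(x)) < 1e-12) {
    warning("uniform image: empty mask")
    return(matrix(FALSE, nrow(x), ncol(x)))
  }
  thr <- if (method == "otsu") EBImage::otsu(EBImage::Image(x), levels = 256)
         else {
           stopifnot(is.numeric(threshold), threshold >= 0, threshold <= 1)
           threshold
         }
  mask <- x > thr
  if (!any(mask)) {
    warning("empty foreground after thresholding")
    return(mask)
  }
  # drop small objects
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  sizes <- tabulate(as.integer(lab))
  keep <- which(sizes >= min_object)
  mask <- matrix(as.integer(lab) %in% keep, nrow(x), ncol(x))
  # fill enclosed holes smaller than max_hole
  holes <- EBImage::bwlabel(EBImage::Image((!mask) * 1))
  hl <- matrix(as.integer(holes), nrow(x), ncol(x))
  border_ids <- unique(c(hl[1, ], hl[nrow(x), ], hl[, 1], hl[, ncol(x)]))
  hsizes <- tabulate(hl)
  fill_ids <- setdiff(which(hsizes <= max_hole), border_ids)
  fill_ids <- setdiff(fill_ids, 0L)
  if (length(fill_ids)) mask[matrix(hl %in% fill_ids, nrow(x))] <- TRUE
  if (!any(mask)) warning("empty mask after cleanup")
  mask
}

# shift a padded matrix; helper for the thinning neighbourhood
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Iterative two-subcycle thinning to a one-pixel-wide, 8-connected
#' skeleton. Written in vectorized R; adequate for micrograph-sized masks.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize_mask <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  m <- mask
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours P2..P9 clockwise from north (row-1)
      p <- list(shift_mat(m, -1, 0), shift_mat(m, -1, 1), shift_mat(m, 0, 1),
                shift_mat(m, 1, 1), shift_mat(m, 1, 0), shift_mat(m, 1, -1),
                shift_mat(m, 0, -1), shift_mat(m, -1, -1))
      bsum <- Reduce(`+`, p)
      # A = number of 0->1 transitions in the ordered circular sequence
      a <- Reduce(`+`, lapply(1:8, function(i)
        (!p[[i]]) & p[[if (i == 8) 1 else i + 1]]))
      if (step == 1) {
        c1 <- !(p[[1]] & p[[3]] & p[[5]])  # P2*P4*P6 = 0
        c2 <- !(p[[3]] & p[[5]] & p[[7]])  # P4*P6*P8 = 0
      } else {
        c1 <- !(p[[1]] & p[[3]] & p[[7]])  # P2*P4*P8 = 0
        c2 <- !(p[[1]] & p[[5]] & p[[7]])  # P2*P6*P8 = 0
      }
      del <- m & bsum >= 2 & bsum <= 6 & a == 1 & c1 & c2
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Sample fiber diameters along the skeleton
#'
#' Skeletonizes the mask and, at each retained skeleton pixel, records a
#' diameter sample from the Euclidean distance transform (EDT):
#' `diameter = (2 * EDT_ridge - 0.5) * pixel_size`, where `EDT_ridge` is the
#' maximum EDT over the pixel's 3 x 3 neighbourhood. The neighbourhood
#' maximum compensates for thinned skeleton pixels sitting up to a pixel off
#' the true medial ridge on obliquely oriented fibers; the half-pixel term
#' corrects for the EDT being measured to background pixel centers (about
#' half a pixel beyond the true boundary) while the best lattice ridge point
#' sits about a quarter pixel inside the medial axis. An axis-aligned ribbon
#' spanning w pixel rows yields samples of w + 0.5 pixels; oblique ribbons
#' are recovered essentially unbiased.
#'
#' Skeleton pixels within one local radius of a skeleton endpoint or
#' junction are excluded, since the distance transform is inflated where
#' fibers cross and the skeleton retracts where they terminate. Endpoints
#' and junctions are classified by the crossing number (the count of
#' background-to-skeleton transitions around the 8-neighbour ring: 1 for an
#' endpoint, >= 3 for a junction), which is robust to the staircase pixels
#' of diagonal skeleton segments.
#'
#' @param mask Logical matrix from [segment_fibers()].
#' @param pixel_size Micrometres per pixel.
#' @return Numeric vector of diameter samples in micrometres, with
#'   attribute `n_excluded` (skeleton pixels dropped by the guard).
#' @export
measure_radii <- function(mask, pixel_size) {
  stopifnot(is.logical(mask), is.matrix(mask),
            is.numeric(pixel_size), pixel_size > 0)
  if (!any(mask)) stop("empty mask: nothing to measure")
  edt <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  skel <- skeletonize_mask(mask)
  nbs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
              c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  # ridge-corrected EDT: max over the 3x3 neighbourhood
  edt_ridge <- edt
  for (d in nbs) {
    sh <- matrix(0, nrow(edt), ncol(edt))
    rs <- max(1, 1 + d[1]):min(nrow(edt), nrow(edt) + d[1])
    cs <- max(1, 1 + d[2]):min(ncol(edt), ncol(edt) + d[2])
    sh[rs, cs] <- edt[rs - d[1], cs - d[2]]
    edt_ridge <- pmax(edt_ridge, sh)
  }
  # endpoint / junction guard via the crossing number
  p <- lapply(nbs, function(d) shift_mat(skel, d[1], d[2]))
  crossings <- Reduce(`+`, lapply(1:8, function(i)
    (!p[[i]]) & p[[if (i == 8) 1 else i + 1]]))
  special <- skel & (crossings == 1 | crossings >= 3)
  keep <- skel
  if (any(special)) {
    # distance from every pixel to the nearest endpoint/junction
    dist_special <- as.matrix(EBImage::distmap(EBImage::Image((!special) * 1)))
    keep <- skel & (dist_special > edt)
  }
  n_excluded <- sum(skel) - sum(keep)
  if (!any(keep))
    stop("all skeleton pixels fell within the endpoint/junction guard")
  samples <- (2 * edt_ridge[keep] - 0.5) * pixel_size
  attr(samples, "n_excluded") <- n_excluded
  samples
}

#' Full diameter statistics with histogram
#'
#' Computes the standard morphometric statistic set for fiber diameter
#' samples: mean, sample SD, mode (center of the most populated histogram
#' bin), median, min, max, Fisher skewness g1, excess kurtosis g2, and the
#' sample count. For an all-equal sample, SD, skewness and kurtosis are 0
#' by convention.
#'
#' @param samples Numeric vector of diameters (um), n >= 2.
#' @param histogram_bin Histogram bin width in um (default 0.05); bins start
#'   at 0.
#' @return A list of class `diameter_stats` with the nine statistics and a
#'   `histogram` data frame (`bin_center`, `count`).
#' @export
diameter_statistics <- function(samples, histogram_bin = 0.05) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("need at least 2 samples")
  if (any(!is.finite(samples))) stop("samples must be finite")
  n <- length(samples)
  m <- mean(samples)
  dev <- samples - m
  m2 <- mean(dev^2); m3 <- mean(dev^3); m4 <- mean(dev^4)
  if (m2 == 0) {
    skew <- 0; kurt <- 0
  } else {
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2 - 3
  }
  breaks <- seq(0, max(samples) + histogram_bin, by = histogram_bin)
  hs <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  mode_center <- hs$mids[which.max(hs$counts)]
  structure(list(mean = m, sd = stats::sd(samples), mode = mode_center,
                 median = stats::median(samples), min = min(samples),
                 max = max(samples), skewness = skew, kurtosis = kurt,
                 n = n,
                 histogram = data.frame(bin_center = hs$mids,
                                        count = hs$counts)),
            class = "diameter_stats")
}

#' @export
print.diameter_stats <- function(x, ...) {
  cat("fiber diameter statistics (um):\n")
  cat(sprintf("  mean %.3g  sd %.3g  mode %.3g  median %.3g\n",
              x$mean, x$sd, x$mode, x$median))
  cat(sprintf("  min %.3g  max %.3g  skewness %.3g  excess kurtosis %.3g  n %d\n",
              x$min, x$max, x$skewness, x$kurtosis, x$n))
  invisible(x)
}

#' @export
as.data.frame.diameter_stats <- function(x, ...) {
  data.frame(mean = x$mean, sd = x$sd, mode = x$mode, median = x$median,
             min = x$min, max = x$max, skewness = x$skewness,
             kurtosis = x$kurtosis, n = x$n)
}
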