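# shared helpers for the cellugel test suite

space_upper <- function() reference_unified_params("space", "upper")
ground_middle <- function() reference_unified_params("ground", "middle")

# standard cellulose II three-peak truth for WAXS generator tests
waxs_truth <- function(areas = c(120, 160, 200), fwhms = c(0.5, 0.45, 0.35)) {
  list(peaks = data.frame(center = unname(d_to_q(cellulose_ii_dspacings())),
                          fwhm = fwhms, area = areas),
       background = c(40, 8, 0.9))
}

# perturb unified params by deterministic factors
perturb_params <- function(p, factors) {
  unified_params(p$background * factors[1], p$G1 * factors[2],
                 p$B1 * factors[3], p$Rg1 * factors[4], p$P1 * factors[5],
                 p$G2 * factors[6], p$B2 * factors[7], p$Rg2 * factors[8],
                 p$P2 * factors[9])
}

# one explicitly laid-out straight ribbon
single_ribbon_config <- function(width_px, orientation = 0, length_px = 80,
                                 size = c(128L, 128L), pixel_size = 1) {
  synth_config("ribbon_image", seed = 1,
               grid = list(size = size, pixel_size = pixel_size),
               truth = list(ribbons = data.frame(
                 row = size[1] / 2, col = size[2] / 2,
                 orientation = orientation, length_px = length_px,
                 width_px = width_px)))
}
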