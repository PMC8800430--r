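#' Per-condition analysis summary
#'
#' Collects the stage outputs for one synthesis condition. Derived
#' comparison quantities (mean peak area, mean FWHM, Rg2 mean +/- SEM, B2
#' uniformity) are never stored: they are recomputed from the stage outputs
#' by [condition_metrics()] and [compare_conditions()].
#'
#' @param condition Condition label.
#' @param saxs_params Data frame with one row per capillary position and at
#'   least the columns `position`, `Rg2`, `B2` (e.g. fitted unified-model
#'   parameters, or a slice of [saxs_reference_table()]).
#' @param peak_table Data frame with columns `position`, `area`, `fwhm_deg`
#'   for the 020 reflection.
#' @param dp_summary A `dp_summary` from [fit_gaussian_envelope()].
#' @param diameter_stats A `diameter_stats` from [diameter_statistics()].
#' @return An object of class `condition_summary`.
#' @export
condition_summary <- function(condition, saxs_params = NULL,
                              peak_table = NULL, dp_summary = NULL,
                              diameter_stats = NULL) {
  for (d in list(saxs_params, peak_table))
    if (!is.null(d) && !all(d$position %in% c("upper", "middle", "bottom")))
      stop("positions must be among upper, middle, bottom")
  structure(list(condition = condition, saxs_params = saxs_params,
                 peak_table = peak_table, dp_summary = dp_summary,
                 diameter_stats = diameter_stats),
            class = "condition_summary")
}

#' Derived metrics of a condition summary
#'
#' Pure function of the stage outputs: mean 020 peak area and FWHM across
#' positions, lamellar Rg2 mean +/- SEM, and the B2 uniformity ratio
#' (max/min of the level-2 power-law prefactor across positions; values
#' near 1 indicate a particle density that is uniform along the capillary).
#'
#' @param x A [condition_summary()].
#' @return List with `mean_area`, `mean_fwhm`, `rg2` ([average_with_sem()]
#'   result), `b2_uniformity`; fields whose inputs are absent are `NULL`.
#' @export
condition_metrics <- function(x) {
  stopifnot(inherits(x, "condition_summary"))
  out <- list(mean_area = NULL, mean_fwhm = NULL, rg2 = NULL,
              b2_uniformity = NULL)
  if (!is.null(x$peak_table)) {
    out$mean_area <- mean(x$peak_table$area)
    out$mean_fwhm <- mean(x$peak_table$fwhm_deg)
  }
  if (!is.null(x$saxs_params)) {
    out$rg2 <- average_with_sem(x$saxs_params$Rg2, digits = 2)
    out$b2_uniformity <- max(x$saxs_params$B2) / min(x$saxs_params$B2)
  }
  out
}

#' Compare two synthesis conditions
#'
#' Computes the headline comparative quantities between condition `a` and
#' condition `b`: the mean-area ratio b/a, the relative FWHM difference
#' (b - a)/a, the Rg2 means +/- SEM, and the per-condition B2 uniformity
#' ratios. Rows whose inputs are missing from either summary are omitted
#' with a warning, never reported as zero.
#'
#' @param a,b [condition_summary()] objects.
#' @return A list of class `condition_comparison` with elements
#'   `conditions`, `area_ratio`, `fwhm_rel_diff`, `rg2`, `b2_uniformity`
#'   (the last two are per-condition named lists).
#' @export
#' @examples
#' tab <- waxs_reference_table()
#' mk <- function(cc) condition_summary(cc,
#'   saxs_params = subset(saxs_reference_table(), condition == cc),
#'   peak_table = subset(tab, condition == cc))
#' cmp <- compare_conditions(mk("space"), mk("ground"))
#' cmp$area_ratio
compare_conditions <- function(a, b) {
  stopifnot(inherits(a, "condition_summary"), inherits(b, "condition_summary"))
  ma <- condition_metrics(a); mb <- condition_metrics(b)
  out <- list(conditions = c(a = a$condition, b = b$condition))
  if (!is.null(ma$mean_area) && !is.null(mb$mean_area)) {
    out$area_ratio <- mb$mean_area / ma$mean_area
  } else warning("peak areas missing: area ratio omitted")
  if (!is.null(ma$mean_fwhm) && !is.null(mb$mean_fwhm)) {
    out$fwhm_rel_diff <- (mb$mean_fwhm - ma$mean_fwhm) / ma$mean_fwhm
  } else warning("FWHMs missing: FWHM contrast omitted")
  if (!is.null(ma$rg2) && !is.null(mb$rg2)) {
    out$rg2 <- stats::setNames(list(ma$rg2, mb$rg2), out$conditions)
  } else warning("Rg2 values missing: Rg2 row omitted")
  if (!is.null(ma$b2_uniformity) && !is.null(mb$b2_uniformity)) {
    out$b2_uniformity <- stats::setNames(
      c(ma$b2_uniformity, mb$b2_uniformity), out$conditions)
  } else warning("B2 values missing: uniformity row omitted")
  structure(out, class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("comparison %s (a) vs %s (b):\n",
              x$conditions[["a"]], x$conditions[["b"]]))
  if (!is.null(x$area_ratio))
    cat(sprintf("  mean 020 area ratio b/a: %.3g\n", x$area_ratio))
  if (!is.null(x$fwhm_rel_diff))
    cat(sprintf("  FWHM relative difference (b-a)/a: %+.1f%%\n",
                100 * x$fwhm_rel_diff))
  if (!is.null(x$rg2))
    for (nm in names(x$rg2))
      cat(sprintf("  Rg2 %s: %.2f +/- %.2f nm\n", nm,
                  x$rg2[[nm]]$mean, x$rg2[[nm]]$sem))
  if (!is.null(x$b2_uniformity))
    for (nm in names(x$b2_uniformity))
      cat(sprintf("  B2 uniformity %s: %.3g\n", nm, x$b2_uniformity[[nm]]))
  invisible(x)
}

pipeline_allowed_keys <- list(
  top = c("seed", "output_dir", "conditions", "saxs", "waxs", "maldi",
          "ribbons"),
  condition = c("saxs", "waxs", "maldi", "ribbons"),
  saxs = c("noise", "n_points", "qmin", "qmax", "reference_condition"),
  waxs = c("noise", "areas", "fwhms", "background"),
  maldi = c("noise", "mean_dp", "dp_sigma", "dp_range"),
  ribbons = c("n_ribbons", "width_mean", "width_sd", "pixel_size", "size"))

validate_pipeline_config <- function(cfg) {
  check <- function(keys, allowed, where) {
    bad <- setdiff(keys, allowed)
    if (length(bad))
      stop("unknown configuration key '", bad[1], "' in ", where)
  }
  check(names(cfg), pipeline_allowed_keys$top, "top level")
  if (is.null(cfg$conditions) || !length(cfg$conditions))
    stop("configuration must list at least one condition")
  for (cname in names(cfg$conditions)) {
    cond <- cfg$conditions[[cname]]
    check(names(cond), pipeline_allowed_keys$condition,
          paste0("condition '", cname, "'"))
    for (stage in names(cond))
      check(names(cond[[stage]]), pipeline_allowed_keys[[stage]],
            paste0(cname, "$", stage))
  }
  invisible(cfg)
}

#' Run the full synthetic-analysis pipeline from a configuration
#'
#' Orchestrates, per condition and capillary position, the four analysis
#' stages on seeded synthetic inputs: SAXS unified-model fits, WAXS
#' background/peak deconvolution with reflection assignment, MALDI DP
#' estimation, and ribbon-width morphometry; then compares the first two
#' conditions. All random draws derive deterministically from the top-level
#' seed, so a rerun with the same configuration reproduces byte-identical
#' tables.
#'
#' The configuration is a YAML file (or an equivalent list) with keys
#' `seed`, `output_dir`, and `conditions`, each condition naming any of the
#' stages `saxs`, `waxs`, `maldi`, `ribbons` with stage parameters (see
#' `pipeline_allowed_keys` in the source; unknown keys fail validation by
#' name). SAXS truth parameters come from [saxs_reference_table()] for the
#' configured `reference_condition`.
#'
#' @param config Path to a YAML file, or a list.
#' @param output_dir Output directory; overrides the configuration.
#' @return Invisibly, a list with the per-condition summaries, the
#'   comparison, and the paths of the written tables.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("missing configuration file: ", config)
    yaml::read_yaml(config)
  } else config
  validate_pipeline_config(cfg)
  seed <- as.integer(cfg$seed %||% 1L)
  out <- output_dir %||% cfg$output_dir %||% stop("no output directory given")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  positions <- c("upper", "middle", "bottom")
  seed_log <- data.frame(stage = character(), seed = integer())
  note_seed <- function(stage, s)
    seed_log <<- rbind(seed_log, data.frame(stage = stage, seed = s))

  summaries <- list()
  saxs_rows <- list(); waxs_rows <- list(); maldi_rows <- list()
  diam_rows <- list()
  for (ci in seq_along(cfg$conditions)) {
    cname <- names(cfg$conditions)[ci]
    cond <- cfg$conditions[[cname]]
    saxs_params <- NULL; peak_table <- NULL; dps <- NULL; dstats <- NULL

    if (!is.null(cond$saxs)) {
      sc <- cond$saxs
      refc <- sc$reference_condition %||% cname
      rows <- lapply(seq_along(positions), function(pi) {
        pos <- positions[pi]
        truth <- reference_unified_params(refc, pos)
        s <- seed + 1000L * ci + 10L * pi
        note_seed(paste("saxs", cname, pos), s)
        g <- generate_saxs_curve(synth_config(
          "saxs", seed = s, noise = sc$noise %||% 0.02,
          grid = list(qmin = sc$qmin %||% 0.07, qmax = sc$qmax %||% 2.5,
                      n = sc$n_points %||% 300L),
          truth = truth))
        fit <- fit_unified_model(g$curve, truth)
        cbind(data.frame(condition = cname, position = pos,
                         chi2_per_point = fit$chi2_per_point,
                         converged = fit$converged),
              as.data.frame(fit$params[c("background", "G1", "B1", "Rg1",
                                         "P1", "G2", "B2", "Rg2", "P2")]))
      })
      saxs_params <- do.call(rbind, rows)
      saxs_rows[[cname]] <- saxs_params
    }

    if (!is.null(cond$waxs)) {
      wc <- cond$waxs
      areas <- unlist(wc$areas %||% c(120, 90, 95))
      fwhms <- unlist(wc$fwhms %||% c(0.40, 0.30, 0.31))
      rows <- lapply(seq_along(positions), function(pi) {
        pos <- positions[pi]
        s <- seed + 1000L * ci + 10L * pi + 1L
        note_seed(paste("waxs", cname, pos), s)
        centers <- d_to_q(cellulose_ii_dspacings())
        peaks <- data.frame(center = centers,
                            fwhm = c(0.5, 0.45, fwhms[pi]),
                            area = c(areas[pi] * 0.6, areas[pi] * 0.8,
                                     areas[pi]))
        g <- generate_waxs_profile(synth_config(
          "waxs", seed = s, noise = wc$noise %||% 0.01,
          truth = list(peaks = peaks,
                       background = unlist(wc$background %||% c(40, 8, 0.9)))))
        wins <- cellulose_peak_windows(qlim = g$profile)
        bg <- estimate_smooth_background(g$profile, wins)
        pf <- fit_peaks(g$profile, bg, wins)
        asg <- assign_reflections(pf)
        i020 <- which(asg$plane == "020")
        data.frame(condition = cname, position = pos,
                   area = pf$area[i020], area_se = pf$area_se[i020],
                   fwhm_deg = pf$fwhm_2theta[i020],
                   fwhm_se = pf$fwhm_q_se[i020])
      })
      peak_table <- do.call(rbind, rows)
      avg <- data.frame(condition = cname, position = "average",
                        area = mean(peak_table$area), area_se = NA,
                        fwhm_deg = mean(peak_table$fwhm_deg), fwhm_se = NA)
      waxs_rows[[cname]] <- rbind(peak_table, avg)
    }

    if (!is.null(cond$maldi)) {
      mc <- cond$maldi
      s <- seed + 1000L * ci + 7L
      note_seed(paste("maldi", cname), s)
      g <- generate_maldi_spectrum(synth_config(
        "maldi", seed = s, noise = mc$noise %||% 0.02,
        truth = list(mean_dp = mc$mean_dp %||% 6.9,
                     dp_sigma = mc$dp_sigma %||% 1.2,
                     dp_range = mc$dp_range %||% c(4L, 11L))))
      series <- pick_series_peaks(g$spectrum)
      dps <- fit_gaussian_envelope(series)
      maldi_rows[[cname]] <- data.frame(
        condition = cname, mean_mw = dps$mean_mw, mean_dp = dps$mean_dp,
        dp_min = dps$dp_min, dp_max = dps$dp_max,
        envelope_sigma = dps$envelope_sigma)
    }

    if (!is.null(cond$ribbons)) {
      rc <- cond$ribbons
      s <- seed + 1000L * ci + 9L
      note_seed(paste("ribbons", cname), s)
      g <- generate_ribbon_image(synth_config(
        "ribbon_image", seed = s,
        grid = list(size = rc$size %||% c(512L, 512L),
                    pixel_size = rc$pixel_size %||% 0.05),
        truth = list(n_ribbons = rc$n_ribbons %||% 120L,
                     width_mean = rc$width_mean %||% 0.254,
                     width_sd = rc$width_sd %||% 0.128)))
      mask <- segment_fibers(g$image)
      dstats <- diameter_statistics(measure_radii(mask, g$image$pixel_size))
      diam_rows[[cname]] <- cbind(data.frame(condition = cname),
                                  as.data.frame(dstats))
    }

    summaries[[cname]] <- condition_summary(
      cname, saxs_params = saxs_params, peak_table = peak_table,
      dp_summary = dps, diameter_stats = dstats)
  }

  comparison <- if (length(summaries) >= 2L)
    compare_conditions(summaries[[1L]], summaries[[2L]])

  wr <- function(rows, file) {
    if (!length(rows)) return(NULL)
    path <- file.path(out, file)
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
    path
  }
  paths <- c(
    saxs = wr(saxs_rows, "saxs_fits.csv"),
    waxs = wr(waxs_rows, "waxs_peaks.csv"),
    maldi = wr(maldi_rows, "maldi_dp.csv"),
    ribbons = wr(diam_rows, "diameter_stats.csv"))
  if (!is.null(comparison)) {
    cmp_df <- data.frame(
      quantity = c("area_ratio_b_over_a", "fwhm_rel_diff",
                   paste0("b2_uniformity_", names(comparison$b2_uniformity)),
                   paste0("rg2_mean_", names(comparison$rg2)),
                   paste0("rg2_sem_", names(comparison$rg2))),
      value = c(comparison$area_ratio, comparison$fwhm_rel_diff,
                unname(comparison$b2_uniformity),
                vapply(comparison$rg2, `[[`, numeric(1), "mean"),
                vapply(comparison$rg2, `[[`, numeric(1), "sem")))
    utils::write.csv(cmp_df, file.path(out, "comparison.csv"),
                     row.names = FALSE)
    paths <- c(paths, comparison = file.path(out, "comparison.csv"))
  }
  log_lines <- c(
    sprintf("cellugel %s on R %s", as.character(utils::packageVersion("cellugel")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("top-level seed: %d", seed),
    sprintf("config digest: %d keys, %d conditions", length(cfg),
            length(cfg$conditions)),
    sprintf("stage seed: %-24s %d", seed_log$stage, seed_log$seed))
  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(list(summaries = summaries, comparison = comparison,
                 paths = paths, seeds = seed_log))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
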