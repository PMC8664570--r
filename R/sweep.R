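#' Sweep and interaction-call configuration
#'
#' The interaction statistic re-runs detection and colocalization at every
#' intensity threshold of an SD sweep (default 1, 2, ..., 25), drops
#' thresholds where an image yields fewer than `min_spots` spots in either
#' channel (to avoid percentages computed from a handful of clusters), and
#' aggregates replicate animals into a mean curve with a Student-t 95%
#' confidence band.
#'
#' @param thresholds strictly increasing SD thresholds (default `1:25`).
#' @param min_spots minimum detected spots per channel per image for a
#'   threshold to contribute (default 15).
#' @param max_distance_px colocalization pairing distance (default 3 px).
#' @param ci_level confidence level for the replicate band (default 0.95).
#' @param exclusion `"both-channels"` (default: a threshold is excluded for a
#'   replicate when either channel falls below `min_spots`) or `"prey-only"`.
#' @param call_rule a [call_rule()].
#' @export
sweep_config <- function(thresholds = 1:25, min_spots = 15L,
                         max_distance_px = 3, ci_level = 0.95,
                         exclusion = c("both-channels", "prey-only"),
                         call_rule = celinc::call_rule()) {
  assert_that(length(thresholds) >= 1L && all(diff(thresholds) > 0),
              "thresholds must be strictly increasing")
  assert_that(is_scalar_num(min_spots) && min_spots >= 1,
              "min_spots must be >= 1")
  assert_that(is_scalar_num(ci_level) && ci_level > 0 && ci_level < 1,
              "ci_level must be in (0, 1)")
  structure(list(thresholds = as.numeric(thresholds),
                 min_spots = as.integer(min_spots),
                 max_distance_px = max_distance_px, ci_level = ci_level,
                 exclusion = match.arg(exclusion), call_rule = call_rule),
            class = "sweep_config")
}

#' Parameters of the interaction classifier
#'
#' The assay protocol reads curve shape by eye ("flat or rapidly decreasing"
#' versus "increasing"); this rule makes that reproducible: a Theil-Sen trend
#' of the mean prey-with-bait fraction against threshold, a bootstrap
#' confidence interval over replicate animals, and a floor on the fraction at
#' the highest usable threshold.
#'
#' @param slope_alpha two-sided alpha for the bootstrap slope interval.
#' @param min_final_fraction positivity floor for the mean prey-with-bait
#'   fraction at the final non-excluded threshold (default 0.25 — a package
#'   decision; the protocol states no numeric floor).
#' @param n_boot bootstrap resamples.
#' @param min_replicates a threshold only enters the call when at least this
#'   many replicate animals contribute to its mean (default 2, capped at the
#'   number available). Guards the verdict against single-animal tail points,
#'   where a handful of surviving spots — often granule fragments present in
#'   both channels — can fake a high coclustering fraction.
#' @export
call_rule <- function(slope_alpha = 0.05, min_final_fraction = 0.25,
                      n_boot = 500L, min_replicates = 2L) {
  structure(list(slope_alpha = slope_alpha,
                 min_final_fraction = min_final_fraction,
                 n_boot = as.integer(n_boot),
                 min_replicates = as.integer(min_replicates)),
            class = "call_rule")
}

# Theil-Sen slope: median of all pairwise slopes.
theil_sen_slope <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  ij <- utils::combn(n, 2L)
  stats::median((y[ij[2L, ]] - y[ij[1L, ]]) / (x[ij[2L, ]] - x[ij[1L, ]]))
}

# Student-t mean CI per column of a matrix with NAs (excluded cells).
t_band <- function(mat, ci_level) {
  n <- colSums(!is.na(mat))
  m <- suppressWarnings(colMeans(mat, na.rm = TRUE))
  m[n == 0L] <- NA_real_
  s <- suppressWarnings(apply(mat, 2L, stats::sd, na.rm = TRUE))
  half <- ifelse(n >= 2L, stats::qt(1 - (1 - ci_level) / 2, pmax(n - 1L, 1L)) *
                   s / sqrt(n), NA_real_)
  list(mean = m, ci_low = m - half, ci_high = m + half, n_used = n)
}

#' Build a sweep curve from per-replicate fraction matrices
#'
#' Rarely called directly: [run_sweep()] produces these. Exposed so curves can
#' be built from externally computed fractions (e.g. plugin result tables).
#' Cells already `NA` stay excluded; additionally any threshold where
#' `n_bait`/`n_prey` fall below `min_spots` (per the exclusion mode) is
#' masked. Excluded cells are absent, never zero.
#'
#' @param thresholds SD thresholds (columns).
#' @param prey replicate x threshold matrix of prey-with-bait fractions.
#' @param bait matching matrix of bait-with-prey fractions (optional).
#' @param n_bait,n_prey replicate x threshold spot-count matrices used for the
#'   exclusion rule (optional; no exclusion when missing).
#' @param config a [sweep_config()].
#' @return a `sweep_curve` with per-replicate values, exclusion flags, and
#'   mean / `ci_low` / `ci_high` / `n_used` per threshold for both directions.
#' @export
sweep_curve <- function(thresholds, prey, bait = NULL, n_bait = NULL,
                        n_prey = NULL, config = sweep_config()) {
  prey <- as.matrix(prey)
  assert_that(ncol(prey) == length(thresholds),
              "prey matrix must have one column per threshold")
  if (is.null(bait)) bait <- matrix(NA_real_, nrow(prey), ncol(prey))
  excluded <- matrix(FALSE, nrow(prey), ncol(prey))
  if (!is.null(n_bait) && !is.null(n_prey)) {
    excluded <- if (config$exclusion == "both-channels") {
      n_bait < config$min_spots | n_prey < config$min_spots
    } else {
      n_prey < config$min_spots
    }
  }
  prey_m <- prey; prey_m[excluded] <- NA_real_
  bait_m <- as.matrix(bait); bait_m[excluded] <- NA_real_
  agg_p <- t_band(prey_m, config$ci_level)
  agg_b <- t_band(bait_m, config$ci_level)
  structure(list(thresholds = as.numeric(thresholds),
                 prey = prey_m, bait = bait_m,
                 n_bait = n_bait, n_prey = n_prey, excluded = excluded,
                 mean = agg_p$mean, ci_low = agg_p$ci_low,
                 ci_high = agg_p$ci_high, n_used = agg_p$n_used,
                 mean_bait = agg_b$mean, ci_low_bait = agg_b$ci_low,
                 ci_high_bait = agg_b$ci_high, n_used_bait = agg_b$n_used,
                 config = config),
            class = "sweep_curve")
}

#' Re-apply the minimum-spot exclusion with a different cutoff
#'
#' Lowering `min_spots` can only add defined thresholds, never remove them.
#'
#' @param curve a `sweep_curve` carrying count matrices.
#' @param min_spots new cutoff.
#' @export
apply_exclusion <- function(curve, min_spots) {
  assert_that(!is.null(curve$n_bait) && !is.null(curve$n_prey),
              "curve carries no spot counts; cannot re-apply exclusion")
  cfg <- curve$config
  cfg$min_spots <- as.integer(min_spots)
  prey <- curve$prey; prey[curve$excluded] <- NA_real_
  # restore raw values where we still have them: excluded cells were masked,
  # so rebuild from the stored raw matrices
  sweep_curve(curve$thresholds, curve$raw_prey %||% curve$prey,
              curve$raw_bait %||% curve$bait,
              curve$n_bait, curve$n_prey, cfg)
}

#' Run the full detection/colocalization threshold sweep
#'
#' For each replicate animal and each SD threshold, both channels are detected
#' (the band-pass filter and ROI statistics are computed once per replicate
#' and reused across thresholds) and colocalized; multiple ROIs within one
#' replicate are pooled by a spot-count-weighted average. A threshold is
#' excluded for a replicate when its image-level spot count falls below
#' `min_spots` (per the configured channel rule). Replicates are then
#' aggregated into mean and t confidence band.
#'
#' @param replicates list of replicates; each is a list with `scene` (an
#'   [image_scene()]) and `rois` (list of [roi_mask()]).
#' @param bait_channel,prey_channel channel names.
#' @param config a [sweep_config()].
#' @param params a [detection_params()]; `threshold_sd` is overridden by the
#'   sweep. Default mirrors the colocalization-mode plugin settings
#'   (particle size 3, larger particles excluded).
#' @return a `sweep_curve`.
#' @export
run_sweep <- function(replicates, bait_channel = "bait",
                      prey_channel = "prey", config = sweep_config(),
                      params = detection_params(include_larger = FALSE)) {
  assert_that(length(replicates) >= 1L, "need at least one replicate")
  nt <- length(config$thresholds)
  nr <- length(replicates)
  prey_f <- matrix(NA_real_, nr, nt)
  bait_f <- matrix(NA_real_, nr, nt)
  nb_m <- matrix(0L, nr, nt)
  np_m <- matrix(0L, nr, nt)
  for (ri in seq_len(nr)) {
    rep_i <- replicates[[ri]]
    scene <- rep_i$scene
    masks <- lapply(rep_i$rois, rasterize_roi,
                    shape = dim(scene$channels[[1L]]),
                    pixel_size = scene$pixel_size)
    raw_b <- scene$channels[[bait_channel]]
    raw_p <- scene$channels[[prey_channel]]
    assert_that(!is.null(raw_b) && !is.null(raw_p),
                "bait/prey channel missing from scene")
    filt_b <- dog_filter(raw_b, params$particle_size_px)
    filt_p <- dog_filter(raw_p, params$particle_size_px)
    stats_b <- lapply(masks, function(m) roi_stats(filt_b, m))
    stats_p <- lapply(masks, function(m) roi_stats(filt_p, m))
    for (ti in seq_len(nt)) {
      thr <- config$thresholds[ti]
      fb <- numeric(0); fp <- numeric(0)
      wb <- numeric(0); wp <- numeric(0)
      nb <- 0L; np <- 0L
      for (mi in seq_along(masks)) {
        tb <- detect_spots_prepared(raw_b, filt_b, masks[[mi]],
                                    stats_b[[mi]], params, thr,
                                    roi_label = attr(masks[[mi]], "label"),
                                    channel = bait_channel)
        tp <- detect_spots_prepared(raw_p, filt_p, masks[[mi]],
                                    stats_p[[mi]], params, thr,
                                    roi_label = attr(masks[[mi]], "label"),
                                    channel = prey_channel)
        res <- colocalize(tb, tp, config$max_distance_px)
        nb <- nb + res$n_bait; np <- np + res$n_prey
        if (res$n_prey > 0L) {
          fp <- c(fp, res$frac_prey_with_bait); wp <- c(wp, res$n_prey)
        }
        if (res$n_bait > 0L) {
          fb <- c(fb, res$frac_bait_with_prey); wb <- c(wb, res$n_bait)
        }
      }
      nb_m[ri, ti] <- nb; np_m[ri, ti] <- np
      if (length(fp)) prey_f[ri, ti] <- stats::weighted.mean(fp, wp)
      if (length(fb)) bait_f[ri, ti] <- stats::weighted.mean(fb, wb)
    }
  }
  curve <- sweep_curve(config$thresholds, prey_f, bait_f, nb_m, np_m, config)
  curve$raw_prey <- prey_f
  curve$raw_bait <- bait_f
  curve
}

#' Tidy data frame of a sweep curve (one row per replicate x threshold)
#' @param curve a `sweep_curve`.
#' @export
sweep_to_df <- function(curve) {
  nr <- nrow(curve$prey); nt <- length(curve$thresholds)
  data.frame(
    replicate = rep(seq_len(nr), times = nt),
    threshold = rep(curve$thresholds, each = nr),
    frac_prey_with_bait = as.vector(curve$prey),
    frac_bait_with_prey = as.vector(curve$bait),
    n_bait = if (!is.null(curve$n_bait)) as.vector(curve$n_bait) else NA,
    n_prey = if (!is.null(curve$n_prey)) as.vector(curve$n_prey) else NA,
    excluded = as.vector(curve$excluded))
}

#' Call a protein-protein interaction from a sweep curve
#'
#' Fits a Theil-Sen trend to the mean prey-with-bait fraction over the defined
#' thresholds, with a percentile bootstrap interval over replicate animals.
#' Verdict:
#' * `positive` — slope interval entirely above 0, final-threshold fraction at
#'   or above `min_final_fraction`, and (when a GFP-only control curve is
#'   supplied) above the control's final-fraction CI upper bound;
#' * `negative` — slope interval at or below 0, or final fraction below the
#'   floor;
#' * `indeterminate` — fewer than 3 defined thresholds, or anything else.
#'
#' The bait-with-prey curve is reported but never used for the verdict.
#'
#' @param curve a `sweep_curve`.
#' @param control optional `sweep_curve` from a GFP-only bait experiment.
#' @param rule a [call_rule()].
#' @return an `interaction_call` list: `verdict`, `slope`, `slope_ci`,
#'   `final_fraction`, `final_threshold`, `evidence` (text trace),
#'   `control_comparison`.
#' @export
call_interaction <- function(curve, control = NULL, rule = call_rule()) {
  # a threshold enters the call only when enough replicates contribute
  need_rep <- max(1L, min(rule$min_replicates %||% 2L,
                          max(curve$n_used, 1L)))
  defined <- which(curve$n_used >= need_rep & is.finite(curve$mean))
  ev <- character(0)
  if (length(defined) < 3L) {
    return(structure(list(verdict = "indeterminate", slope = NA_real_,
                          slope_ci = c(NA_real_, NA_real_),
                          final_fraction = NA_real_,
                          final_threshold = NA_real_,
                          evidence = sprintf(
                            "only %d defined threshold(s); need >= 3",
                            length(defined)),
                          control_comparison = NULL, rule = rule),
                     class = "interaction_call"))
  }
  x <- curve$thresholds[defined]
  y <- curve$mean[defined]
  slope <- theil_sen_slope(x, y)
  nr <- nrow(curve$prey)
  boot_mat <- curve$prey[, defined, drop = FALSE]
  boots <- vapply(seq_len(rule$n_boot), function(b) {
    rows <- sample.int(nr, nr, replace = TRUE)
    m <- colMeans(boot_mat[rows, , drop = FALSE], na.rm = TRUE)
    theil_sen_slope(x, m)
  }, numeric(1))
  boots <- boots[is.finite(boots)]
  a <- rule$slope_alpha
  slope_ci <- if (length(boots)) {
    unname(stats::quantile(boots, c(a / 2, 1 - a / 2), type = 7))
  } else c(NA_real_, NA_real_)
  fin <- defined[length(defined)]
  final_fraction <- curve$mean[fin]
  final_threshold <- curve$thresholds[fin]
  ev <- c(ev, sprintf("Theil-Sen slope %.4g, %d%% bootstrap CI [%.4g, %.4g]",
                      slope, round(100 * (1 - a)), slope_ci[1L], slope_ci[2L]),
          sprintf("final fraction %.3f at threshold %g (floor %.2f)",
                  final_fraction, final_threshold, rule$min_final_fraction))
  control_cmp <- NULL
  control_ok <- TRUE
  if (!is.null(control)) {
    need_c <- max(1L, min(rule$min_replicates %||% 2L,
                          max(control$n_used, 1L)))
    cdef <- which(control$n_used >= need_c & is.finite(control$mean))
    if (length(cdef)) {
      cfin <- cdef[length(cdef)]
      bound <- control$ci_high[cfin]
      if (!is.finite(bound)) bound <- control$mean[cfin]
      control_ok <- final_fraction > bound
      control_cmp <- list(control_final = control$mean[cfin],
                          control_bound = bound, exceeds = control_ok)
      ev <- c(ev, sprintf("control final fraction %.3f (bound %.3f): %s",
                          control$mean[cfin], bound,
                          if (control_ok) "exceeded" else "not exceeded"))
    }
  }
  verdict <- if (!is.na(slope_ci[1L]) && slope_ci[1L] > 0 &&
                 final_fraction >= rule$min_final_fraction && control_ok) {
    "positive"
  } else if ((!is.na(slope_ci[2L]) && slope_ci[2L] <= 0) ||
             final_fraction < rule$min_final_fraction) {
    "negative"
  } else "indeterminate"
  structure(list(verdict = verdict, slope = slope, slope_ci = slope_ci,
                 final_fraction = final_fraction,
                 final_threshold = final_threshold,
                 evidence = ev, control_comparison = control_cmp,
                 rule = rule),
            class = "interaction_call")
}

#' @export
print.interaction_call <- function(x, ...) {
  cat(sprintf("<interaction_call> %s\n", toupper(x$verdict)))
  for (e in x$evidence) cat("  ", e, "\n", sep = "")
  invisible(x)
}
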