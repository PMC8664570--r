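#' Normalize a cluster-count time series
#'
#' Subtracts the pre-illumination count and rescales so the series is exactly
#' 0 at the pre-illumination timepoint and exactly 1 at the maximum:
#' `normalized = (counts - counts[pre_index]) / max(counts - counts[pre_index])`.
#' Ties at the maximum resolve to the earliest timepoint.
#'
#' @param times timepoints (minutes), strictly increasing.
#' @param counts cluster counts per timepoint.
#' @param pre_index index of the pre-illumination timepoint (default 1), or a
#'   `decay_counts` object in `times` (then `counts`/`pre_index` are taken
#'   from it).
#' @return a `decay_series` list: `times`, `counts`, `baseline_count`,
#'   `normalized`, `peak_index`, `pre_index`.
#' @export
normalize_decay <- function(times, counts = NULL, pre_index = 1L) {
  if (inherits(times, "decay_counts")) {
    counts <- times$counts
    pre_index <- times$pre_index
    times <- times$times
  }
  assert_that(length(times) >= 3L && length(counts) == length(times),
              "need >= 3 timepoints with matching counts")
  assert_that(all(diff(times) > 0), "times must be strictly increasing")
  assert_that(pre_index >= 1L && pre_index <= length(times),
              "pre_index out of range")
  baseline <- counts[pre_index]
  shifted <- counts - baseline
  peak <- max(shifted)
  if (peak <= 0) {
    stop("no activation detected: no count exceeds the pre-illumination value",
         call. = FALSE)
  }
  structure(list(times = times, counts = counts, baseline_count = baseline,
                 normalized = shifted / peak,
                 peak_index = which.max(shifted),   # earliest on ties
                 pre_index = pre_index),
            class = "decay_series")
}

#' Estimate the cluster-decay half-life
#'
#' Assumes first-order decay of the baseline-subtracted count after the peak,
#' `N(t) = N0 * (1/2)^((t - t_peak) / t_half)` with `N0` the peak value.
#' Two estimators:
#' * `"pointwise"` — solves the decay equation at each usable post-peak point,
#'   `t_half = (t - t_peak) * log(2) / log(N0 / N(t))`, and reports the mean;
#' * `"loglinear"` (default) — least-squares fit of `log N(t)` against
#'   `t - t_peak` over the peak and post-peak points; `t_half = log(2) /
#'   |slope|`.
#'
#' Post-peak points with non-positive normalized value are skipped with a
#' warning; the peak itself anchors the fit. Both estimators agree exactly on
#' noiseless exponential series.
#'
#' @param series a `decay_series` from [normalize_decay()].
#' @param method `"loglinear"` or `"pointwise"`.
#' @return a `half_life_estimate` list: `t_half`, `n0` (peak count after
#'   baseline subtraction), `method`, `fit_points` (times used), `residual`
#'   (RMS of log-scale residuals; 0 for pointwise on a single point).
#' @export
estimate_half_life <- function(series, method = c("loglinear", "pointwise")) {
  method <- match.arg(method)
  assert_that(inherits(series, "decay_series"),
              "series must come from normalize_decay()")
  pk <- series$peak_index
  t_peak <- series$times[pk]
  post <- which(seq_along(series$times) > pk)
  usable <- post[series$normalized[post] > 0]
  if (length(usable) < length(post)) {
    warning(sprintf("%d post-peak point(s) with normalized value <= 0 skipped",
                    length(post) - length(usable)))
  }
  assert_that(length(usable) >= 1L,
              "need at least one usable post-peak point")
  n0 <- series$counts[pk] - series$baseline_count
  dt <- series$times[usable] - t_peak
  nv <- series$normalized[usable]
  if (method == "pointwise") {
    strict <- nv < 1
    assert_that(any(strict), "all post-peak points sit at the peak value")
    th <- dt[strict] * log(2) / log(1 / nv[strict])
    t_half <- mean(th)
    fit_t <- series$times[usable][strict]
    resid <- stats::sd(th) %||% 0
    if (is.na(resid)) resid <- 0
  } else {
    xs <- c(0, dt)
    ys <- log(c(1, nv))
    fit <- stats::lm.fit(cbind(1, xs), ys)
    slope <- fit$coefficients[2L]
    assert_that(is.finite(slope) && slope < 0,
                "no decay: log-linear slope is not negative")
    t_half <- log(2) / abs(slope)
    fit_t <- c(t_peak, series$times[usable])
    resid <- sqrt(mean(fit$residuals^2))
  }
  structure(list(t_half = unname(t_half), n0 = n0, method = method,
                 fit_points = fit_t, residual = unname(resid),
                 t_peak = t_peak),
            class = "half_life_estimate")
}

#' @export
print.half_life_estimate <- function(x, ...) {
  cat(sprintf("<half_life_estimate> t1/2 = %.3g min (%s, %d fit points)\n",
              x$t_half, x$method, length(x$fit_points)))
  invisible(x)
}

#' Cluster density per 10 square micrometres
#'
#' @param table a `spot_table` (or anything with `nrow()`).
#' @param roi a rasterized ROI (logical mask with an `area_um2` attribute)
#'   or an `area_um2` value.
#' @return a `density_result` data frame row: `roi_label`, `n_spots`,
#'   `area_um2`, `density_per_10um2 = 10 * n_spots / area_um2`.
#' @export
cluster_density <- function(table, roi) {
  area <- if (is.numeric(roi)) roi else attr(roi, "area_um2")
  label <- if (is.numeric(roi)) "roi" else attr(roi, "label") %||% "roi"
  assert_that(is_scalar_num(area) && area > 0, "ROI area must be > 0")
  n <- nrow(table)
  out <- data.frame(roi_label = label, n_spots = n, area_um2 = area,
                    density_per_10um2 = 10 * n / area)
  class(out) <- c("density_result", "data.frame")
  out
}

#' Intensity and size relationships of coclustered spots
#'
#' Over the mutual-nearest-neighbour pairs of a colocalization result, the
#' Pearson and Spearman correlation of bait versus prey background-corrected
#' integrated intensity; and, over all bait spots, the difference in mean
#' pixel area between coclustered and non-coclustered spots plus a binned
#' coclustering probability against area.
#'
#' @param coloc a `coloc_result` from [colocalize()].
#' @param bait,prey the `spot_table`s it was computed from.
#' @param n_bins bins for the probability-versus-area profile.
#' @return list with `n_pairs`, `pearson_r`, `spearman_rho`,
#'   `area_diff` (mean coclustered minus mean non-coclustered bait area),
#'   `mean_area_coclustered`, `mean_area_free`, `prob_by_area` data frame, and
#'   `reason` for any absent value.
#' @export
coclustering_intensity_stats <- function(coloc, bait, prey, n_bins = 5L) {
  out <- list(n_pairs = nrow(coloc$pairs), pearson_r = NA_real_,
              spearman_rho = NA_real_, area_diff = NA_real_,
              mean_area_coclustered = NA_real_, mean_area_free = NA_real_,
              prob_by_area = NULL, reason = NULL)
  if (nrow(coloc$pairs) >= 3L) {
    bi <- coloc$pairs$bait; pi_ <- coloc$pairs$prey
    x <- bait$integrated_intensity[bi]
    y <- prey$integrated_intensity[pi_]
    out$pearson_r <- stats::cor(x, y, method = "pearson")
    out$spearman_rho <- stats::cor(x, y, method = "spearman")
  } else {
    out$reason <- c(out$reason, "fewer than 3 coclustered pairs")
  }
  if (coloc$n_bait > 0L && nrow(prey) > 0L) {
    d <- sqrt(outer(bait$y, prey$y, `-`)^2 + outer(bait$x, prey$x, `-`)^2)
    hit <- rowSums(d <= coloc$max_distance_px) > 0L
    if (any(hit) && any(!hit)) {
      out$mean_area_coclustered <- mean(bait$n_area[hit])
      out$mean_area_free <- mean(bait$n_area[!hit])
      out$area_diff <- out$mean_area_coclustered - out$mean_area_free
      qs <- unique(stats::quantile(bait$n_area, seq(0, 1, length.out = n_bins + 1L)))
      if (length(qs) >= 2L) {
        bin <- cut(bait$n_area, qs, include.lowest = TRUE)
        out$prob_by_area <- data.frame(
          bin = levels(bin),
          mean_area = as.vector(tapply(bait$n_area, bin, mean)),
          p_cocluster = as.vector(tapply(hit, bin, mean)),
          n = as.vector(table(bin)))
      }
    } else {
      out$reason <- c(out$reason,
                      "need >= 1 coclustered and >= 1 free bait spot")
    }
  } else {
    out$reason <- c(out$reason, "empty bait or prey table")
  }
  out
}
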