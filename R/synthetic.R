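#' Cell specification for synthetic scenes
#'
#' Each simulated cell is a polygonal region with a relative expression level
#' that scales both the expected cluster count and the cluster amplitudes
#' within it, mimicking mosaic expression from multicopy transgene arrays.
#'
#' @param polygon vertex matrix (`y`, `x`) in 0-based pixel-centre coordinates.
#' @param expression_level non-negative scalar; 1 is the reference level.
#' @param label optional cell label.
#' @export
cell_spec <- function(polygon, expression_level = 1, label = NULL) {
  polygon <- as.matrix(polygon)
  assert_that(ncol(polygon) == 2L && nrow(polygon) >= 3L,
              "polygon needs >= 3 (y, x) vertices")
  assert_that(is_scalar_num(expression_level) && expression_level >= 0,
              "expression_level must be >= 0")
  structure(list(polygon = polygon, expression_level = expression_level,
                 label = label), class = "cell_spec")
}

# Two rectangular cells filling most of the frame; the default tissue layout.
default_cells <- function(image_shape) {
  h <- image_shape[1L]; w <- image_shape[2L]
  mid <- floor(w / 2)
  rect <- function(r0, r1, c0, c1) {
    cbind(y = c(r0, r0, r1, r1), x = c(c0, c1, c1, c0))
  }
  list(cell_spec(rect(10, h - 11, 8, mid - 8), 1, "cellA"),
       cell_spec(rect(10, h - 11, mid + 8, w - 9), 1, "cellB"))
}

#' Configuration of a synthetic two-channel cluster scene
#'
#' Defaults describe a 256 x 256 px field at 0.2 um/px (51 x 51 um) holding
#' two large intestinal-like cells, diffuse cytoplasmic background with
#' Gaussian read noise, compact bright bait clusters whose peak amplitudes
#' follow a truncated normal, prey signal recruited to a bait cluster with
#' probability `cocluster_prob` (optionally tilted towards bright baits via
#' `intensity_coupling`), unrelated free prey clusters, and large round
#' autofluorescent granules rendered identically in both channels.
#'
#' @param image_shape `c(h, w)` pixels.
#' @param pixel_size um per pixel.
#' @param rng_seed integer seed; identical config + seed gives a bit-identical
#'   scene and ground truth.
#' @param background_level per-channel diffuse background (length-2, bait/prey).
#' @param noise_sigma per-channel Gaussian read-noise sd (> 0).
#' @param cluster_density expected bait clusters per 100 um^2 at expression 1.
#' @param cluster_sigma_px Gaussian radius (sd) of a cluster, pixels.
#' @param cluster_amplitude_mean,cluster_amplitude_sd peak intensity above
#'   background (normal, truncated below at 5% of the mean).
#' @param cocluster_prob baseline probability rho that a bait cluster carries
#'   prey signal.
#' @param intensity_coupling >= 0; log-odds of coclustering increase by this
#'   much per SD of bait amplitude: logit(p_i) = logit(rho) + coupling * z_i.
#' @param prey_free_density expected non-coclustered prey clusters per 100 um^2.
#' @param prey_native_scale amplitude of non-recruited prey puncta relative to
#'   cluster amplitudes (default 0.5: recruited clusters carry roughly twice
#'   the signal of the prey's native localization).
#' @param granule_density expected autofluorescent granules per 100 um^2.
#' @param granule_radius_px granule disk radius, pixels.
#' @param cells list of [cell_spec()] objects.
#' @export
scene_config <- function(image_shape = c(256L, 256L),
                         pixel_size = 0.2,
                         rng_seed = 1L,
                         background_level = c(100, 100),
                         noise_sigma = c(10, 10),
                         cluster_density = 3,
                         cluster_sigma_px = 1,
                         cluster_amplitude_mean = 80,
                         cluster_amplitude_sd = 40,
                         cocluster_prob = 0.8,
                         intensity_coupling = 0,
                         prey_free_density = 1.5,
                         prey_native_scale = 0.5,
                         granule_density = 0.3,
                         granule_radius_px = 6,
                         cells = NULL) {
  if (length(background_level) == 1L) background_level <- rep(background_level, 2L)
  if (length(noise_sigma) == 1L) noise_sigma <- rep(noise_sigma, 2L)
  cfg <- list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
              rng_seed = rng_seed, background_level = background_level,
              noise_sigma = noise_sigma, cluster_density = cluster_density,
              cluster_sigma_px = cluster_sigma_px,
              cluster_amplitude_mean = cluster_amplitude_mean,
              cluster_amplitude_sd = cluster_amplitude_sd,
              cocluster_prob = cocluster_prob,
              intensity_coupling = intensity_coupling,
              prey_free_density = prey_free_density,
              prey_native_scale = prey_native_scale,
              granule_density = granule_density,
              granule_radius_px = granule_radius_px,
              cells = cells %||% default_cells(image_shape))
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  assert_that(length(cfg$image_shape) == 2L && all(cfg$image_shape >= 16L),
              "image_shape must be (h, w), each >= 16")
  assert_that(is_scalar_num(cfg$pixel_size) && cfg$pixel_size > 0,
              "pixel_size must be > 0")
  assert_that(all(cfg$noise_sigma > 0), "noise_sigma must be > 0")
  assert_that(all(cfg$background_level >= 0), "background_level must be >= 0")
  assert_that(is_scalar_num(cfg$cocluster_prob) &&
                cfg$cocluster_prob >= 0 && cfg$cocluster_prob <= 1,
              "cocluster_prob must be in [0, 1]")
  assert_that(is_scalar_num(cfg$intensity_coupling) &&
                cfg$intensity_coupling >= 0,
              "intensity_coupling must be >= 0")
  assert_that(is_scalar_num(cfg$prey_native_scale) && cfg$prey_native_scale > 0,
              "prey_native_scale must be > 0")
  for (f in c("cluster_density", "prey_free_density", "granule_density")) {
    assert_that(is_scalar_num(cfg[[f]]) && cfg[[f]] >= 0,
                sprintf("%s must be >= 0", f))
  }
  assert_that(length(cfg$cells) >= 1L &&
                all(vapply(cfg$cells, inherits, logical(1), "cell_spec")),
              "cells must be a list of cell_spec")
  h <- cfg$image_shape[1L]; w <- cfg$image_shape[2L]
  for (cs in cfg$cells) {
    p <- cs$polygon
    assert_that(all(p[, 1L] >= -0.5 & p[, 1L] <= h - 0.5 &
                    p[, 2L] >= -0.5 & p[, 2L] <= w - 0.5),
                "cell polygon outside image bounds")
    assert_that(polygon_area_px(p) > 0, "zero-area cell polygon")
  }
  invisible(cfg)
}

# Uniform points inside a polygon by rejection sampling in its bounding box.
sample_in_polygon <- function(n, poly) {
  if (n == 0L) return(cbind(y = numeric(0), x = numeric(0)))
  ylim <- range(poly[, 1L]); xlim <- range(poly[, 2L])
  ys <- numeric(0); xs <- numeric(0)
  while (length(ys) < n) {
    m <- max(16L, 2L * (n - length(ys)))
    py <- stats::runif(m, ylim[1L], ylim[2L])
    px <- stats::runif(m, xlim[1L], xlim[2L])
    keep <- point_in_polygon(py, px, poly)
    ys <- c(ys, py[keep]); xs <- c(xs, px[keep])
  }
  cbind(y = ys[seq_len(n)], x = xs[seq_len(n)])
}

# Add an isotropic Gaussian bump of peak `amp` and sd `sigma` at (y, x)
# (0-based pixel-centre coordinates) to matrix `img`, in place-by-value.
add_gaussian_spot <- function(img, y, x, amp, sigma) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(4 * sigma)
  r0 <- max(1L, floor(y) + 1L - r); r1 <- min(h, ceiling(y) + 1L + r)
  c0 <- max(1L, floor(x) + 1L - r); c1 <- min(w, ceiling(x) + 1L + r)
  if (r0 > r1 || c0 > c1) return(img)
  yy <- (r0:r1) - 1; xx <- (c0:c1) - 1
  g <- exp(-outer((yy - y)^2, (xx - x)^2, `+`) / (2 * sigma^2))
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + amp * g
  img
}

# Add a flat disk of value `amp` and radius `rad` px at (y, x).
add_disk <- function(img, y, x, amp, rad) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(rad)
  r0 <- max(1L, floor(y) + 1L - r); r1 <- min(h, ceiling(y) + 1L + r)
  c0 <- max(1L, floor(x) + 1L - r); c1 <- min(w, ceiling(x) + 1L + r)
  if (r0 > r1 || c0 > c1) return(img)
  yy <- (r0:r1) - 1; xx <- (c0:c1) - 1
  inside <- outer((yy - y)^2, (xx - x)^2, `+`) <= rad^2
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + amp * inside
  img
}

# Truncated-normal amplitude draw (floor at 5% of the mean, never <= 0).
draw_amplitudes <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  lo <- max(mean * 0.05, 1e-6)
  a <- stats::rnorm(n, mean, sd)
  while (any(a < lo)) a[a < lo] <- stats::rnorm(sum(a < lo), mean, sd)
  a
}

#' Simulate a two-channel bait/prey cluster scene with ground truth
#'
#' Bait clusters are placed uniformly inside each cell with a Poisson count of
#' mean `cluster_density / 100 * area_um2 * expression_level`; amplitudes are
#' scaled by the cell's expression level. Each bait cluster recruits a prey
#' cluster with probability `p_i`, where
#' `logit(p_i) = logit(cocluster_prob) + intensity_coupling * z_i` and `z_i`
#' is the bait amplitude standardised by the configured amplitude
#' distribution. Recruited prey sit on the bait centre plus isotropic jitter
#' (sd 0.5 px) with amplitude proportional to the bait's. Free prey clusters
#' and autofluorescent granules (flat disks, identical in both channels) are
#' added on top; Gaussian read noise is applied last and intensities are
#' clipped at zero.
#'
#' @param config a [scene_config()].
#' @return list with elements `scene` ([image_scene()] with channels `bait`
#'   and `prey`), `truth` (a `ground_truth` list: `bait_spots`, `prey_spots`
#'   data frames, `per_cell_counts`), and `config`.
#' @export
simulate_scene <- function(config) {
  validate_scene_config(config)
  with_seed(config$rng_seed, {
    truth <- sample_ground_truth(config)
    scene <- render_scene(truth, config, noise = TRUE)
    list(scene = scene, truth = truth, config = config)
  })
}

# Draw all spot placements (no pixels touched) — the ground truth.
sample_ground_truth <- function(cfg) {
  px_area_um2 <- cfg$pixel_size^2
  bait <- list(); prey <- list()
  per_cell <- integer(length(cfg$cells))
  for (ci in seq_along(cfg$cells)) {
    cs <- cfg$cells[[ci]]
    area_um2 <- polygon_area_px(cs$polygon) * px_area_um2
    n_bait <- stats::rpois(1L, cfg$cluster_density / 100 * area_um2 *
                             cs$expression_level)
    per_cell[ci] <- n_bait
    if (n_bait > 0L) {
      pos <- sample_in_polygon(n_bait, cs$polygon)
      amp <- draw_amplitudes(n_bait, cfg$cluster_amplitude_mean,
                             cfg$cluster_amplitude_sd) *
        max(cs$expression_level, 0)
      bait[[length(bait) + 1L]] <-
        data.frame(y = pos[, 1L], x = pos[, 2L], amplitude = amp,
                   is_granule = FALSE, cell = ci)
    }
    n_free <- stats::rpois(1L, cfg$prey_free_density / 100 * area_um2)
    if (n_free > 0L) {
      pos <- sample_in_polygon(n_free, cs$polygon)
      amp <- cfg$prey_native_scale *
        draw_amplitudes(n_free, cfg$cluster_amplitude_mean,
                        cfg$cluster_amplitude_sd)
      prey[[length(prey) + 1L]] <-
        data.frame(y = pos[, 1L], x = pos[, 2L], amplitude = amp,
                   cocluster_with = NA_integer_, cell = ci)
    }
    n_gran <- stats::rpois(1L, cfg$granule_density / 100 * area_um2)
    if (n_gran > 0L) {
      pos <- sample_in_polygon(n_gran, cs$polygon)
      amp <- draw_amplitudes(n_gran, cfg$cluster_amplitude_mean,
                             cfg$cluster_amplitude_sd)
      bait[[length(bait) + 1L]] <-
        data.frame(y = pos[, 1L], x = pos[, 2L], amplitude = amp,
                   is_granule = TRUE, cell = ci)
    }
  }
  bait_df <- if (length(bait)) do.call(rbind, bait) else
    data.frame(y = numeric(0), x = numeric(0), amplitude = numeric(0),
               is_granule = logical(0), cell = integer(0))
  rownames(bait_df) <- NULL
  # coclustered prey: one per bait cluster with amplitude-tilted probability
  real <- which(!bait_df$is_granule)
  if (length(real) && cfg$cocluster_prob > 0) {
    z <- if (cfg$cluster_amplitude_sd > 0) {
      (bait_df$amplitude[real] - cfg$cluster_amplitude_mean) /
        cfg$cluster_amplitude_sd
    } else rep(0, length(real))
    p <- stats::plogis(stats::qlogis(cfg$cocluster_prob) +
                         cfg$intensity_coupling * z)
    hit <- stats::runif(length(real)) < p
    if (any(hit)) {
      idx <- real[hit]
      jit_y <- stats::rnorm(length(idx), 0, 0.5)
      jit_x <- stats::rnorm(length(idx), 0, 0.5)
      gain <- pmax(stats::rnorm(length(idx), 1, 0.1), 0.2)
      prey[[length(prey) + 1L]] <-
        data.frame(y = bait_df$y[idx] + jit_y, x = bait_df$x[idx] + jit_x,
                   amplitude = bait_df$amplitude[idx] * gain,
                   cocluster_with = idx, cell = bait_df$cell[idx])
    }
  }
  prey_df <- if (length(prey)) do.call(rbind, prey) else
    data.frame(y = numeric(0), x = numeric(0), amplitude = numeric(0),
               cocluster_with = integer(0), cell = integer(0))
  rownames(prey_df) <- NULL
  structure(list(bait_spots = bait_df, prey_spots = prey_df,
                 per_cell_counts = per_cell),
            class = "ground_truth")
}

#' Render a ground truth into a two-channel scene
#'
#' Deterministic given the truth when `noise = FALSE`; `simulate_scene()` is
#' exactly `render_scene(sample_ground_truth(cfg), cfg, noise = TRUE)` under
#' the configured seed, so every rendered spot corresponds to one ground-truth
#' row (conservation by construction, and testable).
#'
#' @param truth a `ground_truth`.
#' @param config the originating [scene_config()].
#' @param noise add Gaussian read noise?
#' @export
render_scene <- function(truth, config, noise = TRUE) {
  h <- config$image_shape[1L]; w <- config$image_shape[2L]
  bait <- matrix(config$background_level[1L], h, w)
  prey <- matrix(config$background_level[2L], h, w)
  bd <- truth$bait_spots
  for (i in seq_len(nrow(bd))) {
    if (bd$is_granule[i]) {
      bait <- add_disk(bait, bd$y[i], bd$x[i], bd$amplitude[i],
                       config$granule_radius_px)
      prey <- add_disk(prey, bd$y[i], bd$x[i], bd$amplitude[i],
                       config$granule_radius_px)
    } else {
      bait <- add_gaussian_spot(bait, bd$y[i], bd$x[i], bd$amplitude[i],
                                config$cluster_sigma_px)
    }
  }
  pd <- truth$prey_spots
  for (i in seq_len(nrow(pd))) {
    prey <- add_gaussian_spot(prey, pd$y[i], pd$x[i], pd$amplitude[i],
                              config$cluster_sigma_px)
  }
  if (noise) {
    bait <- bait + stats::rnorm(h * w, 0, config$noise_sigma[1L])
    prey <- prey + stats::rnorm(h * w, 0, config$noise_sigma[2L])
  }
  image_scene(list(bait = pmax(bait, 0), prey = pmax(prey, 0)),
              config$pixel_size,
              provenance = list(source = "simulate_scene",
                                rng_seed = config$rng_seed))
}

#' Simulate a thin z-stack around a 2D scene (I/O testing helper)
#'
#' Replicates the noise-free 2D signal over `n_slices` with fresh per-slice
#' read noise, so a maximum projection recovers (approximately) the scene.
#'
#' @inheritParams simulate_scene
#' @param n_slices number of z slices.
#' @return list with `stack` (4D array), `truth`, `config`.
#' @export
simulate_scene_stack <- function(config, n_slices = 5L) {
  validate_scene_config(config)
  with_seed(config$rng_seed, {
    truth <- sample_ground_truth(config)
    clean <- render_scene(truth, config, noise = FALSE)
    h <- config$image_shape[1L]; w <- config$image_shape[2L]
    arr <- array(0, dim = c(n_slices, 2L, h, w))
    for (z in seq_len(n_slices)) {
      arr[z, 1L, , ] <- pmax(clean$channels$bait +
        stats::rnorm(h * w, 0, config$noise_sigma[1L]), 0)
      arr[z, 2L, , ] <- pmax(clean$channels$prey +
        stats::rnorm(h * w, 0, config$noise_sigma[2L]), 0)
    }
    attr(arr, "channel_names") <- c("bait", "prey")
    list(stack = arr, truth = truth, config = config)
  })
}

#' Write a simulated scene bundle to disk
#'
#' TIFF (channels as a 1-slice ZCYX stack), ground truth as CSV (one row per
#' spot: channel, y, x, amplitude, cocluster partner index, granule flag,
#' cell), ROIs as JSON and the configuration echoed as JSON.
#'
#' @param sim result of [simulate_scene()].
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return invisible named list of written paths.
#' @export
write_scene_bundle <- function(sim, dir, stem = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    tiff = file.path(dir, paste0(stem, ".tif")),
    truth = file.path(dir, paste0(stem, "_truth.csv")),
    rois = file.path(dir, paste0(stem, "_rois.json")),
    config = file.path(dir, paste0(stem, "_config.json")))
  write_stack(sim$scene, paths$tiff, channel_names = names(sim$scene$channels))
  bd <- sim$truth$bait_spots; pd <- sim$truth$prey_spots
  truth_df <- rbind(
    data.frame(channel = rep("bait", nrow(bd)), y = bd$y, x = bd$x,
               amplitude = bd$amplitude, cocluster_with = NA_integer_,
               is_granule = bd$is_granule, cell = bd$cell),
    data.frame(channel = rep("prey", nrow(pd)), y = pd$y, x = pd$x,
               amplitude = pd$amplitude, cocluster_with = pd$cocluster_with,
               is_granule = FALSE, cell = pd$cell))
  utils::write.csv(truth_df, paths$truth, row.names = FALSE)
  rois <- lapply(seq_along(sim$config$cells), function(i) {
    cs <- sim$config$cells[[i]]
    roi_mask(cs$label %||% paste0("cell", i), cs$polygon)
  })
  write_rois(rois, paths$rois)
  cfg <- sim$config
  cfg$cells <- lapply(cfg$cells, function(cs) {
    list(label = cs$label, expression_level = cs$expression_level,
         polygon = lapply(seq_len(nrow(cs$polygon)),
                          function(i) unname(cs$polygon[i, ])))
  })
  jsonlite::write_json(unclass(cfg), paths$config, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Configuration of a simulated cluster-decay time course
#'
#' Models the count of light-induced clusters over time: flat at
#' `baseline_count` before illumination (t = 0), a linear rise to
#' `peak_count` at `peak_time`, then first-order exponential decay back
#' towards baseline with half-life `t_half`:
#' `E[N(t)] = baseline + (peak - baseline) * (1/2)^((t - peak_time)/t_half)`.
#'
#' @param t_half decay half-life, minutes (> 0).
#' @param baseline_count mean pre-illumination cluster count (>= 0).
#' @param peak_count mean count at maximum (> baseline_count).
#' @param peak_time minutes after illumination at which the maximum occurs;
#'   the observed maximum is at +6 min in the motivating experiments.
#' @param sample_times strictly increasing sampling times, minutes; negative
#'   times are pre-illumination.
#' @param count_noise `"poisson"`, or a Gaussian sd (0 = noiseless).
#' @param rng_seed integer seed.
#' @export
decay_sim_config <- function(t_half = 34, baseline_count = 10,
                             peak_count = 110, peak_time = 6,
                             sample_times = c(-1, 0, seq(1, 26, by = 5)),
                             count_noise = "poisson", rng_seed = 1L) {
  assert_that(is_scalar_num(t_half) && t_half > 0, "t_half must be > 0")
  assert_that(is_scalar_num(baseline_count) && baseline_count >= 0,
              "baseline_count must be >= 0")
  assert_that(is_scalar_num(peak_count) && peak_count > baseline_count,
              "peak_count must exceed baseline_count")
  assert_that(is_scalar_num(peak_time) && peak_time >= 0,
              "peak_time must be >= 0")
  assert_that(length(sample_times) >= 3L && all(diff(sample_times) > 0),
              "sample_times must be strictly increasing (>= 3 points)")
  assert_that(any(sample_times < 0),
              "sample_times must include a pre-illumination (< 0) point")
  ok_noise <- identical(count_noise, "poisson") ||
    (is_scalar_num(count_noise) && count_noise >= 0)
  assert_that(ok_noise, "count_noise must be \"poisson\" or a Gaussian sd")
  structure(list(t_half = t_half, baseline_count = baseline_count,
                 peak_count = peak_count, peak_time = peak_time,
                 sample_times = sample_times, count_noise = count_noise,
                 rng_seed = rng_seed),
            class = "decay_sim_config")
}

#' Expected cluster count of the decay model at time t
#' @param config a [decay_sim_config()].
#' @param t times in minutes.
#' @export
decay_expected <- function(config, t) {
  b <- config$baseline_count; p <- config$peak_count
  pt <- config$peak_time
  out <- numeric(length(t))
  pre <- t < 0
  rise <- !pre & t <= pt
  post <- t > pt
  out[pre] <- b
  out[rise] <- if (pt > 0) b + (p - b) * t[rise] / pt else p
  out[post] <- b + (p - b) * 0.5^((t[post] - pt) / config$t_half)
  out
}

#' Simulate observed cluster counts over a decay time course
#'
#' @param config a [decay_sim_config()].
#' @return a `decay_counts` list: `times`, `counts`, `pre_index` (last
#'   pre-illumination sample) and `truth` (the config).
#' @export
simulate_decay_counts <- function(config) {
  assert_that(inherits(config, "decay_sim_config"), "need a decay_sim_config")
  mu <- decay_expected(config, config$sample_times)
  counts <- with_seed(config$rng_seed, {
    if (identical(config$count_noise, "poisson")) {
      stats::rpois(length(mu), mu)
    } else if (config$count_noise > 0) {
      pmax(stats::rnorm(length(mu), mu, config$count_noise), 0)
    } else mu
  })
  structure(list(times = config$sample_times, counts = counts,
                 pre_index = max(which(config$sample_times < 0)),
                 truth = config),
            class = "decay_counts")
}
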