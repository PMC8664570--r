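#' Detection parameters (ComDet-style semantics)
#'
#' The detector reimplements the parameter contract of the ImageJ/FIJI
#' ComDet spot-detection plugin this assay protocol is built around: an
#' intensity threshold expressed in SD units of the (robust) background, and
#' flags controlling how particles larger than the approximate size are
#' handled. The algorithm itself is this package's own (documented in the
#' methods vignette); bit-exact agreement with the Java plugin is not a goal.
#'
#' @param particle_size_px approximate particle diameter in pixels (> 0).
#' @param threshold_sd intensity threshold k in SD units (> 0). Candidate
#'   pixels are those whose band-pass-filtered value exceeds
#'   `median + k * SD`, both computed robustly (median/MAD) within the ROI on
#'   the filtered image.
#' @param include_larger keep particles larger than the size cutoff
#'   (`pi * particle_size_px^2` pixels)? If `FALSE` they are dropped — this is
#'   what excludes large round autofluorescent granules in colocalization
#'   mode.
#' @param segment_larger if `TRUE`, oversized particles are watershed-split on
#'   their local maxima instead of kept whole.
#' @param min_pixels minimum component size in pixels (default 3; single-pixel
#'   noise spikes are never reported).
#' @export
detection_params <- function(particle_size_px = 3, threshold_sd = 5,
                             include_larger = TRUE, segment_larger = FALSE,
                             min_pixels = 3L) {
  assert_that(is_scalar_num(particle_size_px) && particle_size_px > 0,
              "particle_size_px must be > 0")
  assert_that(is_scalar_num(threshold_sd) && threshold_sd > 0,
              "threshold_sd must be > 0")
  assert_that(is_scalar_num(min_pixels) && min_pixels >= 1,
              "min_pixels must be >= 1")
  structure(list(particle_size_px = particle_size_px,
                 threshold_sd = threshold_sd,
                 include_larger = isTRUE(include_larger),
                 segment_larger = isTRUE(segment_larger),
                 min_pixels = as.integer(min_pixels)),
            class = "detection_params")
}

# Separable Gaussian blur with replicate edge padding.
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  h <- nrow(img); w <- ncol(img)
  # pad by edge replication
  ridx <- c(rep(1L, r), seq_len(h), rep(h, r))
  cidx <- c(rep(1L, r), seq_len(w), rep(w, r))
  p <- img[ridx, cidx]
  # convolve rows
  out <- matrix(0, h, w + 2L * r)
  for (i in seq_along(k)) {
    out <- out + k[i] * p[i:(i + h - 1L), ]
  }
  res <- matrix(0, h, w)
  for (i in seq_along(k)) {
    res <- res + k[i] * out[, i:(i + w - 1L)]
  }
  res
}

# Band-pass (difference of Gaussians) used before thresholding.
dog_filter <- function(img, particle_size_px) {
  s_small <- max(particle_size_px / 4, 0.5)
  s_large <- 2 * particle_size_px
  gaussian_blur(img, s_small) - gaussian_blur(img, s_large)
}

# Label 8-connected components among candidate pixels (linear indices into an
# h x w matrix). Iterative minimum-label propagation over a precomputed
# neighbour map; returns per-pixel component ids (1..n_components).
label_components <- function(idx, h, w) {
  n <- length(idx)
  if (n == 0L) return(integer(0))
  ord <- order(idx)
  idx <- idx[ord]
  r <- (idx - 1L) %% h + 1L
  cc <- (idx - 1L) %/% h + 1L
  offs <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
               c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  nbr <- matrix(NA_integer_, n, 8L)
  for (k in seq_along(offs)) {
    rr <- r + offs[[k]][1L]; cn <- cc + offs[[k]][2L]
    valid <- rr >= 1L & rr <= h & cn >= 1L & cn <= w
    cand <- ifelse(valid, (cn - 1L) * h + rr, NA_integer_)
    nbr[, k] <- match(cand, idx)
  }
  lab <- seq_len(n)
  repeat {
    new_lab <- lab
    for (k in 1:8) {
      has <- !is.na(nbr[, k])
      new_lab[has] <- pmin(new_lab[has], lab[nbr[has, k]])
    }
    # chase one level of indirection to speed convergence
    new_lab <- pmin(new_lab, new_lab[new_lab])
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  comp <- match(lab, sort(unique(lab)))
  out <- integer(n)
  out[ord] <- comp
  out
}

# ROI-level robust background stats on the filtered image.
roi_stats <- function(filtered, mask) {
  v <- filtered[mask]
  list(med = stats::median(v), sd = robust_sd(v))
}

#' Detect fluorescent clusters in one channel within an ROI
#'
#' Pipeline: (1) difference-of-Gaussians band-pass with
#' `sigma_small = particle_size_px / 4` (floor 0.5) and
#' `sigma_large = 2 * particle_size_px`; (2) robust background statistics
#' (median, MAD-based SD) of the filtered image inside the mask;
#' (3) candidate pixels above `median + threshold_sd * SD`; (4) 8-connected
#' components, dropping those below `min_pixels`; (5) components larger than
#' `pi * particle_size_px^2` px dropped (`include_larger = FALSE`), kept whole
#' (`include_larger = TRUE, segment_larger = FALSE`) or watershed-split on
#' local maxima (`segment_larger = TRUE`); (6) per spot: intensity-weighted
#' centroid on the raw image, pixel area `n_area`, local background (median of
#' a 2-px-wide annulus around the component, excluding other candidates), and
#' `integrated_intensity = sum(raw) - background * n_area`.
#'
#' Spots are ordered by centre `(y, x)`. A zero-variance region returns an
#' empty table flagged with `attr(, "warning")`.
#'
#' @param scene an [image_scene()].
#' @param channel channel name.
#' @param mask logical ROI mask (from [rasterize_roi()]).
#' @param params a [detection_params()].
#' @return a `spot_table` data frame with columns `roi_label`, `channel`, `y`,
#'   `x`, `n_area`, `integrated_intensity`, `peak_value`, `threshold_sd_used`;
#'   component pixel indices in `attr(, "pixels")`.
#' @export
detect_spots <- function(scene, channel, mask, params = detection_params()) {
  assert_that(inherits(scene, "image_scene"), "scene must be an image_scene")
  raw <- scene$channels[[channel]]
  assert_that(!is.null(raw), sprintf("no channel named '%s'", channel))
  assert_that(is.logical(mask) && identical(dim(mask), dim(raw)),
              "mask must be a logical matrix matching the image")
  support <- (2L * ceiling(3 * 2 * params$particle_size_px) + 1L)^2
  assert_that(sum(mask) >= support,
              "mask smaller than the band-pass filter support")
  filtered <- dog_filter(raw, params$particle_size_px)
  st <- roi_stats(filtered, mask)
  detect_spots_prepared(raw, filtered, mask, st, params,
                        params$threshold_sd,
                        roi_label = attr(mask, "label") %||% "roi",
                        channel = channel)
}

# Threshold-specific detection given precomputed raw/filtered/stats.
detect_spots_prepared <- function(raw, filtered, mask, st, params,
                                  threshold_sd, roi_label = "roi",
                                  channel = "ch") {
  h <- nrow(raw); w <- ncol(raw)
  empty <- function(warning = NULL) {
    t <- data.frame(roi_label = character(0), channel = character(0),
                    y = numeric(0), x = numeric(0), n_area = integer(0),
                    integrated_intensity = numeric(0),
                    peak_value = numeric(0), threshold_sd_used = numeric(0))
    attr(t, "pixels") <- list()
    if (!is.null(warning)) attr(t, "warning") <- warning
    class(t) <- c("spot_table", "data.frame")
    t
  }
  if (st$sd <= 0) return(empty("zero-variance region: no detection possible"))
  cut <- st$med + threshold_sd * st$sd
  cand <- which(mask & filtered > cut)
  if (length(cand) == 0L) return(empty())
  comp <- label_components(cand, h, w)
  sizes <- tabulate(comp)
  # seeds: 3x3 local maxima of the filtered image among candidate pixels,
  # in components of at least min_pixels
  ok_comp <- sizes[comp] >= params$min_pixels
  is_seed <- ok_comp & is_local_max(cand, filtered, h, w)
  seed_cand <- cand[is_seed]
  seed_comp <- comp[is_seed]
  if (length(seed_cand) == 0L) return(empty())
  # brightness suppression: drop any seed with a brighter surviving seed
  # within particle_size_px; a suppressor always outlives its suppressee as
  # the threshold rises, so spot counts are non-increasing in threshold_sd
  keep <- suppress_seeds(seed_cand, filtered[seed_cand], h,
                         params$particle_size_px)
  seed_cand <- seed_cand[keep]
  seed_comp <- seed_comp[keep]
  # oversized components: the size veto / whole-vs-split flags
  size_cutoff <- pi * params$particle_size_px^2
  big_ids <- which(sizes > size_cutoff)
  if (length(big_ids)) {
    in_big <- seed_comp %in% big_ids
    if (!params$include_larger) {
      seed_cand <- seed_cand[!in_big]
      seed_comp <- seed_comp[!in_big]
    } else if (!params$segment_larger && any(in_big)) {
      # keep only the brightest seed of each oversized component
      fvals <- filtered[seed_cand]
      drop <- logical(length(seed_cand))
      for (id in unique(seed_comp[in_big])) {
        members <- which(seed_comp == id)
        drop[members[-which.max(fvals[members])]] <- TRUE
      }
      seed_cand <- seed_cand[!drop]
      seed_comp <- seed_comp[!drop]
    }
  }
  if (length(seed_cand) == 0L) return(empty())
  # partition candidate pixels of retained components among their seeds
  sel <- comp %in% unique(seed_comp)
  px <- cand[sel]
  lab <- assign_pixels_to_seeds(px, comp[sel], seed_cand, seed_comp,
                                filtered, h)
  measure_spots(px, lab, raw, cand, h, w, mask, threshold_sd,
                roi_label, channel)
}

# TRUE for candidate pixels that are 3x3 local maxima of `img` (ties allowed:
# >= all neighbours; suppression resolves plateaus deterministically).
is_local_max <- function(idx, img, h, w) {
  r <- (idx - 1L) %% h + 1L
  cc <- (idx - 1L) %/% h + 1L
  v <- img[idx]
  out <- rep(TRUE, length(idx))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    rr <- r + dr; cn <- cc + dc
    valid <- rr >= 1L & rr <= h & cn >= 1L & cn <= w
    nb <- rep(-Inf, length(idx))
    nb[valid] <- img[(cn[valid] - 1L) * h + rr[valid]]
    out <- out & v >= nb
  }
  out
}

# Greedy brightness suppression: process seeds from brightest to dimmest,
# keep a seed iff no already-kept seed lies within `radius` px. Brightness
# ties break by linear pixel index (deterministic).
suppress_seeds <- function(idx, vals, h, radius) {
  n <- length(idx)
  if (n <= 1L) return(rep(TRUE, n))
  r <- (idx - 1L) %% h
  cc <- (idx - 1L) %/% h
  ord <- order(-vals, idx)
  keep <- logical(n)
  kr <- numeric(0); kc <- numeric(0)
  r2 <- radius^2
  for (i in ord) {
    if (length(kr) == 0L || min((kr - r[i])^2 + (kc - cc[i])^2) > r2) {
      keep[i] <- TRUE
      kr <- c(kr, r[i]); kc <- c(kc, cc[i])
    }
  }
  keep
}

# Assign each retained candidate pixel to the nearest seed of its component
# (ties -> brighter seed). Returns labels 1..n_seeds.
assign_pixels_to_seeds <- function(px, px_comp, seed_cand, seed_comp,
                                   filtered, h) {
  lab <- integer(length(px))
  pr <- (px - 1L) %% h; pc <- (px - 1L) %/% h
  sr <- (seed_cand - 1L) %% h; sc <- (seed_cand - 1L) %/% h
  f <- filtered[seed_cand]
  for (id in unique(seed_comp)) {
    seeds <- which(seed_comp == id)
    members <- which(px_comp == id)
    if (length(seeds) == 1L) {
      lab[members] <- seeds
    } else {
      seeds <- seeds[order(-f[seeds])]     # ties -> brightest marker
      d2 <- outer(pr[members], sr[seeds], `-`)^2 +
        outer(pc[members], sc[seeds], `-`)^2
      lab[members] <- seeds[max.col(-d2, ties.method = "first")]
    }
  }
  match(lab, sort(unique(lab)))
}

# Vectorised per-component measurements.
measure_spots <- function(px, lab, raw, all_cand, h, w, mask, threshold_sd,
                          roi_label, channel) {
  n_comp <- max(lab)
  r <- (px - 1L) %% h + 1L; cc <- (px - 1L) %/% h + 1L
  v <- raw[px]
  wsum <- rowsum(v, lab)[, 1L]
  cy <- rowsum(v * (r - 1), lab)[, 1L] / wsum
  cx <- rowsum(v * (cc - 1), lab)[, 1L] / wsum
  n_area <- tabulate(lab, nbins = n_comp)
  peak <- vapply(split(v, factor(lab, levels = seq_len(n_comp))), max,
                 numeric(1))
  # 2-px annulus background: dilate each component by Chebyshev radius 2,
  # exclude every candidate pixel (any component), take the median raw value.
  offs <- expand.grid(dr = -2:2, dc = -2:2)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  nbr_r <- rep(r, times = nrow(offs)) + rep(offs$dr, each = length(px))
  nbr_c <- rep(cc, times = nrow(offs)) + rep(offs$dc, each = length(px))
  nbr_l <- rep(lab, times = nrow(offs))
  ok <- nbr_r >= 1L & nbr_r <= h & nbr_c >= 1L & nbr_c <= w
  nbr_i <- (nbr_c[ok] - 1L) * h + nbr_r[ok]
  nbr_l <- nbr_l[ok]
  in_cand <- nbr_i %in% all_cand
  nbr_i <- nbr_i[!in_cand]; nbr_l <- nbr_l[!in_cand]
  key <- !duplicated(paste0(nbr_l, "_", nbr_i))
  nbr_i <- nbr_i[key]; nbr_l <- nbr_l[key]
  bg <- rep(stats::median(raw[mask]), n_comp)   # fallback: ROI median
  if (length(nbr_i)) {
    med_by <- tapply(raw[nbr_i], nbr_l, stats::median)
    bg[as.integer(names(med_by))] <- med_by
  }
  integ <- wsum - bg * n_area
  ord <- order(cy, cx)
  out <- data.frame(roi_label = rep(roi_label, n_comp),
                    channel = rep(channel, n_comp),
                    y = cy[ord], x = cx[ord],
                    n_area = n_area[ord],
                    integrated_intensity = integ[ord],
                    peak_value = peak[ord],
                    threshold_sd_used = rep(threshold_sd, n_comp))
  rownames(out) <- NULL
  attr(out, "pixels") <- lapply(ord, function(l) px[lab == l])
  class(out) <- c("spot_table", "data.frame")
  out
}

#' Per-spot and aggregate intensity statistics for a spot table
#'
#' Reports the mean peak intensity and the fold-enrichment of the mean raw
#' intensity inside spots over the mean raw intensity of the masked region
#' outside all spots — the "how much brighter are clusters than the rest of
#' the cell" summary.
#'
#' @param table a `spot_table` from [detect_spots()].
#' @param scene the originating [image_scene()].
#' @param channel channel name.
#' @param mask the ROI mask used for detection.
#' @return list with `n_spots`, `mean_peak`, `mean_in`, `mean_out`,
#'   `fold_enrichment` (NA with a `reason` when the table is empty).
#' @export
spot_snr_summary <- function(table, scene, channel, mask) {
  raw <- scene$channels[[channel]]
  assert_that(!is.null(raw), sprintf("no channel named '%s'", channel))
  pixels <- attr(table, "pixels")
  if (nrow(table) == 0L || length(pixels) == 0L) {
    return(list(n_spots = 0L, mean_peak = NA_real_, mean_in = NA_real_,
                mean_out = NA_real_, fold_enrichment = NA_real_,
                reason = "no spots detected"))
  }
  in_px <- unique(unlist(pixels))
  out_mask <- mask
  out_mask[in_px] <- FALSE
  mean_in <- mean(raw[in_px])
  mean_out <- if (any(out_mask)) mean(raw[out_mask]) else NA_real_
  list(n_spots = nrow(table),
       mean_peak = mean(table$peak_value),
       mean_in = mean_in,
       mean_out = mean_out,
       fold_enrichment = mean_in / mean_out)
}
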