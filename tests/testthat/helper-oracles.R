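# Independent oracles and small fixture builders shared across test files.
# Every oracle here is deliberately written as plain, slow, obviously-correct
# code, independent of the package's vectorised implementations.

# Scalar crossing-number point-in-polygon, looped pixel by pixel.
oracle_pip_mask <- function(poly, shape) {
  h <- shape[1]; w <- shape[2]
  mask <- matrix(FALSE, h, w)
  n <- nrow(poly)
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      py <- r - 1; px <- cc - 1
      inside <- FALSE
      j <- n
      for (i in seq_len(n)) {
        yi <- poly[i, 1]; xi <- poly[i, 2]
        yj <- poly[j, 1]; xj <- poly[j, 2]
        if ((yi > py) != (yj > py)) {
          xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
          if (px < xint) inside <- !inside
        }
        j <- i
      }
      mask[r, cc] <- inside
    }
  }
  mask
}

# Brute-force 3x3 local maxima of `img` above `cut`, restricted to `mask`.
# Returns a matrix of 0-based (y, x) positions.
oracle_local_maxima <- function(img, mask, cut) {
  h <- nrow(img); w <- ncol(img)
  out <- NULL
  for (r in 2:(h - 1)) {
    for (cc in 2:(w - 1)) {
      if (!mask[r, cc] || img[r, cc] <= cut) next
      patch <- img[(r - 1):(r + 1), (cc - 1):(cc + 1)]
      if (img[r, cc] == max(patch)) out <- rbind(out, c(r - 1, cc - 1))
    }
  }
  if (is.null(out)) matrix(numeric(0), 0, 2) else out
}

# All-pairs O(n^2) colocalization oracle: per-channel hit flags.
oracle_coloc <- function(bait, prey, max_dist) {
  bait_hit <- logical(nrow(bait))
  prey_hit <- logical(nrow(prey))
  for (i in seq_len(nrow(bait))) {
    for (j in seq_len(nrow(prey))) {
      d <- sqrt((bait$y[i] - prey$y[j])^2 + (bait$x[i] - prey$x[j])^2)
      if (d <= max_dist) { bait_hit[i] <- TRUE; prey_hit[j] <- TRUE }
    }
  }
  list(bait_hit = bait_hit, prey_hit = prey_hit)
}

# Greedy nearest-pair matching (benchmark matcher for well-separated spots):
# returns the number of matched pairs within `max_dist`.
match_spots <- function(a, b, max_dist) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0L)
  d <- sqrt(outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2)
  n_match <- 0L
  repeat {
    m <- which.min(d)
    if (!length(m) || d[m] > max_dist || !is.finite(d[m])) break
    i <- (m - 1) %% nrow(d) + 1
    j <- (m - 1) %/% nrow(d) + 1
    n_match <- n_match + 1L
    d[i, ] <- Inf
    d[, j] <- Inf
    if (all(!is.finite(d))) break
  }
  n_match
}

# A small single-cell scene config for fast detection tests.
small_scene_config <- function(seed, ..., side = 128L) {
  poly <- cbind(y = c(10, 10, side - 11, side - 11),
                x = c(10, side - 11, side - 11, 10))
  scene_config(image_shape = c(side, side), rng_seed = seed,
               cells = list(cell_spec(poly, 1, "cell1")), ...)
}

small_mask <- function(cfg) {
  rasterize_roi(roi_mask("cell1", cfg$cells[[1]]$polygon),
                cfg$image_shape, cfg$pixel_size)
}

# Plain spot tables (enough structure for colocalize()) from coordinates.
coord_table <- function(y, x) {
  data.frame(y = y, x = x, n_area = rep(5L, length(y)),
             integrated_intensity = rep(100, length(y)),
             peak_value = rep(50, length(y)))
}

# Ground-truth sweep oracle: coclustering fractions computed straight from the
# truth tables by thresholding on true amplitude (no detection involved).
oracle_truth_fractions <- function(truth, amp_cuts, max_dist = 3) {
  vapply(amp_cuts, function(cut) {
    b <- truth$bait_spots[!truth$bait_spots$is_granule &
                            truth$bait_spots$amplitude > cut, ]
    p <- truth$prey_spots[truth$prey_spots$amplitude > cut, ]
    if (nrow(p) == 0) return(NA_real_)
    hits <- oracle_coloc(b, p, max_dist)$prey_hit
    mean(hits)
  }, numeric(1))
}
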