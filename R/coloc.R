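#' Object-based bait/prey colocalization
#'
#' A bait spot coclusters iff at least one prey centre lies within
#' centre-to-centre Euclidean distance `max_distance_px` (boundary inclusive),
#' and symmetrically for prey. The two one-sided fractions — prey-with-bait
#' and bait-with-prey — are the assay's readouts; the pairs list (reported by
#' mutual nearest neighbour) is informational.
#'
#' @param bait,prey `spot_table`s from the same scene/ROI.
#' @param max_distance_px maximum pairing distance in pixels (>= 0; the source
#'   experiments use 3).
#' @return a `coloc_result` list: counts `n_bait`, `n_prey`, `n_bait_coloc`,
#'   `n_prey_coloc`; fractions `frac_bait_with_prey`, `frac_prey_with_bait`
#'   (`NA` when the denominator is 0); `max_distance_px`; `pairs` data frame
#'   (`bait`, `prey`, `distance`) of mutual nearest neighbours.
#' @export
colocalize <- function(bait, prey, max_distance_px = 3) {
  assert_that(is_scalar_num(max_distance_px) && max_distance_px >= 0,
              "max_distance_px must be >= 0")
  nb <- nrow(bait); np <- nrow(prey)
  if (nb == 0L || np == 0L) {
    return(structure(list(
      n_bait = nb, n_prey = np, n_bait_coloc = 0L, n_prey_coloc = 0L,
      frac_bait_with_prey = if (nb > 0L) 0 else NA_real_,
      frac_prey_with_bait = if (np > 0L) 0 else NA_real_,
      max_distance_px = max_distance_px,
      pairs = data.frame(bait = integer(0), prey = integer(0),
                         distance = numeric(0))), class = "coloc_result"))
  }
  d <- sqrt(outer(bait$y, prey$y, `-`)^2 + outer(bait$x, prey$x, `-`)^2)
  within <- d <= max_distance_px
  bait_hit <- rowSums(within) > 0L
  prey_hit <- colSums(within) > 0L
  # mutual nearest neighbours among in-range pairs, for reporting
  nn_of_bait <- apply(d, 1L, which.min)
  nn_of_prey <- apply(d, 2L, which.min)
  bi <- seq_len(nb)
  mutual <- nn_of_prey[nn_of_bait] == bi &
    within[cbind(bi, nn_of_bait)]
  pairs <- data.frame(bait = bi[mutual], prey = nn_of_bait[mutual],
                      distance = d[cbind(bi[mutual], nn_of_bait[mutual])])
  structure(list(
    n_bait = nb, n_prey = np,
    n_bait_coloc = sum(bait_hit), n_prey_coloc = sum(prey_hit),
    frac_bait_with_prey = mean(bait_hit),
    frac_prey_with_bait = mean(prey_hit),
    max_distance_px = max_distance_px,
    pairs = pairs), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(paste0("<coloc_result> bait %d (%.1f%% with prey), ",
                     "prey %d (%.1f%% with bait), max distance %.3g px\n"),
              x$n_bait, 100 * x$frac_bait_with_prey,
              x$n_prey, 100 * x$frac_prey_with_bait, x$max_distance_px))
  invisible(x)
}
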