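# Scene and decay simulators: determinism, degenerate cases, and the
# statistical contracts the downstream analysis relies on.

test_that("identical config and seed give bit-identical scenes and truth", {
  cfg <- small_scene_config(17, intensity_coupling = 1.5)
  a <- simulate_scene(cfg)
  b <- simulate_scene(cfg)
  expect_identical(a$scene$channels, b$scene$channels)
  expect_identical(a$truth, b$truth)
  # the generator must not disturb the caller's RNG stream
  set.seed(5); before <- rnorm(3)
  set.seed(5); invisible(simulate_scene(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("zero densities give pure background plus noise and empty truth", {
  cfg <- small_scene_config(2, cluster_density = 0, prey_free_density = 0,
                            granule_density = 0)
  sim <- simulate_scene(cfg)
  expect_equal(nrow(sim$truth$bait_spots), 0L)
  expect_equal(nrow(sim$truth$prey_spots), 0L)
  expect_equal(sim$truth$per_cell_counts, 0L)
  b <- sim$scene$channels$bait
  expect_lt(abs(mean(b) - cfg$background_level[1]), 1)
  expect_lt(abs(sd(b) - cfg$noise_sigma[1]), 0.5)
})

test_that("rendered scene equals render of its own ground truth", {
  cfg <- small_scene_config(23, granule_density = 1)
  sim <- simulate_scene(cfg)
  # re-render the recorded truth without noise and compare to a fresh
  # noiseless render: every truth row maps to exactly one rendered spot
  r1 <- render_scene(sim$truth, cfg, noise = FALSE)
  r2 <- render_scene(sim$truth, cfg, noise = FALSE)
  expect_identical(r1$channels, r2$channels)
  n_exp <- nrow(sim$truth$bait_spots) + nrow(sim$truth$prey_spots)
  above <- sum(r1$channels$bait > cfg$background_level[1] + 1) > 0
  expect_true(n_exp == 0 || above)
  # per-cell counts bookkeeping
  bd <- sim$truth$bait_spots
  expect_equal(sum(sim$truth$per_cell_counts), sum(!bd$is_granule))
})

test_that("cocluster_prob = 1 links every bait to a prey; rho = 0 links none", {
  cfg1 <- small_scene_config(5, cocluster_prob = 1, intensity_coupling = 0,
                             prey_free_density = 0)
  t1 <- simulate_scene(cfg1)$truth
  real <- which(!t1$bait_spots$is_granule)
  expect_true(length(real) > 0)
  expect_setequal(t1$prey_spots$cocluster_with, real)
  # recruited prey sit within ~3 px of their bait (0.5 px jitter)
  d <- sqrt((t1$prey_spots$y - t1$bait_spots$y[t1$prey_spots$cocluster_with])^2 +
            (t1$prey_spots$x - t1$bait_spots$x[t1$prey_spots$cocluster_with])^2)
  expect_true(all(d < 3))

  cfg0 <- small_scene_config(6, cocluster_prob = 0, intensity_coupling = 2)
  t0 <- simulate_scene(cfg0)$truth
  expect_true(all(is.na(t0$prey_spots$cocluster_with)))
})

test_that("coclustered fraction follows the binomial law at rho = 0.5", {
  # pool bait spots over seeds until > 500 trials, then check the exact
  # binomial 99% interval around rho
  n_bait <- 0L; n_co <- 0L; seed <- 100L
  while (n_bait < 500L) {
    cfg <- small_scene_config(seed, cocluster_prob = 0.5,
                              intensity_coupling = 0, prey_free_density = 0,
                              granule_density = 0)
    tr <- simulate_scene(cfg)$truth
    n_bait <- n_bait + sum(!tr$bait_spots$is_granule)
    n_co <- n_co + sum(!is.na(tr$prey_spots$cocluster_with))
    seed <- seed + 1L
  }
  ci <- stats::binom.test(n_co, n_bait, 0.5, conf.level = 0.99)$conf.int
  expect_gte(0.5, ci[1])
  expect_lte(0.5, ci[2])
})

test_that("doubling expression_level doubles expected per-cell counts", {
  tot <- c(0, 0)
  for (seed in 1:30) {
    poly1 <- cbind(y = c(10, 10, 100, 100), x = c(10, 100, 100, 10))
    poly2 <- cbind(y = c(10, 10, 100, 100), x = c(120, 210, 210, 120))
    cfg <- scene_config(image_shape = c(112, 224), rng_seed = 400 + seed,
                        cells = list(cell_spec(poly1, 1, "lo"),
                                     cell_spec(poly2, 2, "hi")),
                        granule_density = 0)
    tr <- simulate_scene(cfg)$truth
    tot <- tot + tr$per_cell_counts
  }
  # same polygon area, expression 2 vs 1: Poisson ratio ~ 2
  z <- (tot[2] - 2 * tot[1]) / sqrt(tot[2] + 4 * tot[1])
  expect_lt(abs(z), 3.5)
})

test_that("intensity coupling makes coclustering odds increase with amplitude", {
  amps <- numeric(0); hits <- logical(0)
  for (seed in 51:58) {
    cfg <- small_scene_config(seed, cocluster_prob = 0.5,
                              intensity_coupling = 1.5,
                              prey_free_density = 0, granule_density = 0,
                              side = 192L)
    tr <- simulate_scene(cfg)$truth
    real <- which(!tr$bait_spots$is_granule)
    amps <- c(amps, tr$bait_spots$amplitude[real])
    hits <- c(hits, real %in% tr$prey_spots$cocluster_with)
  }
  expect_gt(length(amps), 200)
  fit <- stats::glm(hits ~ amps, family = stats::binomial())
  expect_gt(stats::coef(fit)[2], 0)
  # binned probabilities: top quartile exceeds bottom quartile
  qs <- stats::quantile(amps, c(0.25, 0.75))
  expect_gt(mean(hits[amps >= qs[2]]), mean(hits[amps <= qs[1]]))
})

test_that("decay simulator honours the half-life definition and limits", {
  cfg <- decay_sim_config(t_half = 34, baseline_count = 10, peak_count = 110,
                          peak_time = 6,
                          sample_times = c(-1, 0, 6, 6 + 34, 6 + 340),
                          count_noise = 0)
  s <- simulate_decay_counts(cfg)
  expect_equal(s$counts[3], 110)                    # at the peak
  expect_equal(s$counts[4], 10 + (110 - 10) / 2)    # one half-life later
  expect_lt(abs(s$counts[5] - 10), 0.1)             # t -> infinity: baseline
  expect_equal(s$counts[1], 10)                     # pre-illumination
  expect_error(decay_sim_config(peak_count = 5, baseline_count = 10),
               "exceed")
  expect_error(decay_sim_config(sample_times = c(0, 5, 10)),
               "pre-illumination")
})

test_that("poisson decay counts match expectation within 3 SE (moment oracle)", {
  times <- c(-1, 0, 5, 10, 15, 20)
  sums <- numeric(length(times))
  for (seed in 1:100) {
    cfg <- decay_sim_config(t_half = 30, baseline_count = 20,
                            peak_count = 200, peak_time = 5,
                            sample_times = times, count_noise = "poisson",
                            rng_seed = seed)
    sums <- sums + simulate_decay_counts(cfg)$counts
  }
  mu <- decay_expected(decay_sim_config(t_half = 30, baseline_count = 20,
                                        peak_count = 200, peak_time = 5,
                                        sample_times = times), times)
  se <- sqrt(100 * mu)   # Poisson variance = mean
  expect_true(all(abs(sums - 100 * mu) <= 3 * se))
})

test_that("config validation rejects invalid worlds", {
  expect_error(small_scene_config(1, cocluster_prob = 1.2), "cocluster_prob")
  expect_error(small_scene_config(1, noise_sigma = 0), "noise_sigma")
  expect_error(small_scene_config(1, cluster_density = -1), "cluster_density")
  out_poly <- cbind(y = c(-10, -10, 5), x = c(0, 5, 5))
  expect_error(scene_config(image_shape = c(64, 64),
                            cells = list(cell_spec(out_poly))),
               "outside image bounds")
  flat <- cbind(y = c(1, 1, 1), x = c(0, 5, 9))
  expect_error(scene_config(image_shape = c(64, 64),
                            cells = list(cell_spec(flat))), "zero-area")
})

test_that("scene bundles round-trip through disk", {
  sim <- simulate_scene(small_scene_config(9, granule_density = 1))
  dir <- withr::local_tempdir()
  paths <- write_scene_bundle(sim, dir, stem = "s1")
  expect_true(all(file.exists(unlist(paths))))
  stk <- read_stack(paths$tiff)
  expect_equal(dim(stk)[2], 2L)
  truth <- utils::read.csv(paths$truth)
  expect_equal(sum(truth$channel == "bait"), nrow(sim$truth$bait_spots))
  expect_equal(sum(truth$is_granule), sum(sim$truth$bait_spots$is_granule))
  rois <- read_rois(paths$rois)
  expect_equal(length(rois), length(sim$config$cells))
})
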