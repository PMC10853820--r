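test_that("identical config and seed reproduce the scene bitwise", {
  cfg <- tiny_config()
  a <- simulate_cell(cfg, seed = 42)
  b <- simulate_cell(cfg, seed = 42)
  expect_identical(a$scene$channels, b$scene$channels)
  expect_identical(a$truth$rna_positions, b$truth$rna_positions)
  c <- simulate_cell(cfg, seed = 43)
  expect_false(identical(a$scene$channels$rna, c$scene$channels$rna))
})

test_that("configuration errors name the offending field", {
  expect_error(scene_config(pixel_size = 0), "pixel_size")
  expect_error(scene_config(rna_astral_bias = -1), "rna_astral_bias")
  expect_error(scene_config(centrosome_separation = 25, cell_radius = 10),
               "centrosome_separation")
  expect_error(scene_config(stage_label = "anaphase"), "stage_label")
})

ring_angles <- function(sim) {
  # spot angles about each centrosome, measured from its astral direction
  tr <- sim$truth
  sp <- tr$rna_positions[tr$rna_positions$type == "centrosomal", ]
  unlist(lapply(1:2, function(k) {
    s <- sp[sp$centrosome_id == k, ]
    mu <- atan2(tr$spindle_axes[k, 1], tr$spindle_axes[k, 2])
    th <- atan2(s$y_um - tr$centrosome_centers[k, 1],
                s$x_um - tr$centrosome_centers[k, 2]) - mu
    atan2(sin(th), cos(th))
  }))
}

test_that("kappa = 0 gives a uniform ring: resultant length < 0.15 over 500 spots", {
  sim <- simulate_cell(tiny_config(n_rna_centrosomal = 250,
                                   rna_astral_bias = 0), seed = 5)
  th <- ring_angles(sim)
  expect_length(th, 500)
  R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  expect_lt(R, 0.15)
})

test_that("kappa = 4 concentrates ring spots on the astral direction", {
  sim <- simulate_cell(tiny_config(n_rna_centrosomal = 250,
                                   rna_astral_bias = 4), seed = 6)
  th <- ring_angles(sim)   # already relative to the astral direction
  mean_dir <- atan2(mean(sin(th)), mean(cos(th)))
  expect_lt(abs(mean_dir), 0.2)
  # resultant length agrees with a direct von Mises sampling oracle
  th_oracle <- withr::with_seed(7, {
    n <- 500; out <- numeric(0)
    while (length(out) < n) {     # wrapped-normal-free rejection sampling
      cand <- runif(n, -pi, pi)
      keep <- runif(n) < exp(4 * (cos(cand) - 1))
      out <- c(out, cand[keep])
    }
    out[1:n]
  })
  R <- function(x) sqrt(mean(cos(x))^2 + mean(sin(x))^2)
  expect_lt(abs(R(th) - R(th_oracle)), 0.08)
})

test_that("noise-free RNA photon count matches the analytic PSF integral", {
  cfg <- tiny_config(n_rna_centrosomal = 5, n_rna_free = 0, noise = FALSE,
                     background_level = 0, read_noise_sd = 0)
  sim <- simulate_cell(cfg, seed = 8)
  total <- sum(sim$scene$channels$rna)
  sigma_px <- cfg$psf_sigma / cfg$pixel_size
  expected <- 10 * cfg$channel_amplitudes[["rna"]] * 2 * pi * sigma_px^2
  expect_lt(abs(total - expected) / expected, 0.01)
})

test_that("astral axes point away from the inter-centrosome midpoint", {
  for (s in 1:10) {
    tr <- simulate_cell(tiny_config(n_rna_free = 0), seed = s)$truth
    mid <- colMeans(tr$centrosome_centers)
    for (k in 1:2) {
      expect_equal(sqrt(sum(tr$spindle_axes[k, ]^2)), 1, tolerance = 1e-12)
      expect_gt(sum(tr$spindle_axes[k, ] *
                      (tr$centrosome_centers[k, ] - mid)), 0)
    }
  }
})

test_that("doubling a channel amplitude doubles its mean signal (within 3 SE)", {
  n_seeds <- 50
  total_sig <- function(amp_rna, seed) {
    cfg <- tiny_config(channel_amplitudes = c(marker = 800, rna = amp_rna,
                                              protein = 150, dna = 30))
    ch <- simulate_cell(cfg, seed = seed)$scene$channels$rna
    sum(ch) - length(ch) * cfg$background_level
  }
  s1 <- vapply(1:n_seeds, function(s) total_sig(50, s), numeric(1))
  s2 <- vapply(1:n_seeds, function(s) total_sig(100, 1000 + s), numeric(1))
  diff <- mean(s2) - 2 * mean(s1)
  se <- sqrt(var(s2) / n_seeds + 4 * var(s1) / n_seeds)
  expect_lt(abs(diff), 3 * se)
})

test_that("washout ramp arithmetic drives per-timepoint centrosomal counts", {
  kin <- washout_kinetics(lag = 3, recover_fraction = 0.6, end_time = 4,
                          timepoints = c(0, 3, 4))
  expect_equal(recovery_fraction(kin, 0), 0)
  expect_equal(recovery_fraction(kin, 3), 0)      # ramp starts at the lag
  expect_equal(recovery_fraction(kin, 4), 0.6)
  cfg <- tiny_config(n_rna_centrosomal = 20, n_rna_free = 3)
  sims <- simulate_timecourse(cfg, kin, n_cells_per_timepoint = 1, seed = 3)
  counts <- vapply(seq_len(nrow(sims)), function(i) {
    rp <- sims$truth[[i]]$rna_positions
    sum(rp$type == "centrosomal" & rp$centrosome_id == 1)
  }, numeric(1))
  expect_equal(counts[sims$timepoint == 0], 0)
  expect_equal(counts[sims$timepoint == 3], 0)
  expect_equal(counts[sims$timepoint == 4], 12)   # round(20 * 0.6)
  frees <- vapply(seq_len(nrow(sims)), function(i)
    sum(sims$truth[[i]]$rna_positions$type == "free"), numeric(1))
  expect_true(all(frees == 3))
})

test_that("time-course simulation is deterministic and validates its inputs", {
  cfg <- tiny_config(n_rna_free = 5)
  kin <- washout_kinetics(timepoints = c(0, 4))
  a <- simulate_timecourse(cfg, kin, 2, seed = 11)
  b <- simulate_timecourse(cfg, kin, 2, seed = 11)
  expect_identical(lapply(a$scene, `[[`, "channels"),
                   lapply(b$scene, `[[`, "channels"))
  expect_error(simulate_timecourse(cfg, kin, 0, seed = 1),
               "n_cells_per_timepoint")
  expect_error(washout_kinetics(recover_fraction = 1.2), "recover_fraction")
  expect_error(washout_kinetics(lag = 5, end_time = 4), "lag")
  expect_error(washout_kinetics(timepoints = c(1, 2)), "timepoints")
})
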