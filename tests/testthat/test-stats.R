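test_that("Welch test agrees with a first-principles oracle", {
  withr::with_seed(1, {
    for (r in 1:20) {
      a <- rnorm(sample(3:15, 1), sd = runif(1, 0.5, 2))
      b <- rnorm(sample(3:15, 1), mean = runif(1, -1, 1))
      got <- two_sample_t(a, b)
      ref <- welch_oracle(a, b)
      expect_equal(got$statistic, ref$t, tolerance = 1e-10)
      expect_equal(got$p_value, ref$p, tolerance = 1e-10)
    }
  })
})

test_that("degenerate and trivial t-test cases behave as stated", {
  x <- c(1, 2, 3, 4, 5)
  idem <- two_sample_t(x, x)
  expect_equal(idem$statistic, 0)
  expect_equal(idem$p_value, 1)
  sep <- two_sample_t(x, x + 10)
  expect_lt(sep$p_value, 0.001)
  zv <- two_sample_t(c(2, 2, 2), c(2, 2))
  expect_equal(zv$p_value, 1)
  expect_equal(two_sample_t(c(1, 1), c(3, 3))$p_value, 0)
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})

test_that("power-based sample sizing is small for large effects and monotone", {
  n <- required_n(2, alpha = 0.05, power = 0.8)
  expect_lte(n, 7)
  # simulated power at the returned n reaches the target
  rej <- withr::with_seed(2, mean(vapply(1:4000, function(i)
    t.test(rnorm(n), rnorm(n, mean = 2))$p.value < 0.05, logical(1))))
  expect_gte(rej, 0.8 - 0.03)
  expect_gt(required_n(2, power = 0.999), n)
  expect_gt(required_n(0.3), required_n(0.8))
  expect_error(required_n(0), "effect_size")
})

sim_tc <- function(means, n = 12, sd = 1, seed = 1) {
  withr::with_seed(seed, dplyr::bind_rows(purrr::imap(means, function(m, nm)
    tibble::tibble(timepoint = as.numeric(nm),
                   enrichment = rnorm(n, m, sd)))))
}

test_that("recovery onset finds the first truly elevated timepoint", {
  tc <- sim_tc(c(`0` = 0, `1` = 0, `2` = 0, `3` = 5, `4` = 6), seed = 3)
  rr <- recovery_onset(tc, alpha = 0.05)
  expect_s3_class(rr, "recovery_result")
  expect_equal(rr$onset, 3)
  expect_true(all(tidy(rr)$p_value >= 0 & tidy(rr)$p_value <= 1,
                  na.rm = TRUE))
  g <- glance(rr)
  expect_equal(g$onset, 3)
  # baseline comparison: final mean 6 is below a baseline of 10
  rb <- recovery_onset(tc, alpha = 0.05, baseline_mean = 10)
  expect_true(rb$below_baseline)
  rb2 <- recovery_onset(tc, alpha = 0.05, baseline_mean = 2)
  expect_false(rb2$below_baseline)
})

test_that("a purely negative shift never counts as recovery", {
  tc <- sim_tc(c(`0` = 0, `1` = -5, `2` = -6), seed = 4)
  expect_true(is.na(recovery_onset(tc, alpha = 0.05)$onset))
})

test_that("null time-courses rarely produce a spurious onset", {
  k <- 4
  hits <- vapply(1:300, function(s) {
    tc <- sim_tc(setNames(rep(0, k + 1), as.character(0:k)), seed = 500 + s)
    !is.na(recovery_onset(tc, alpha = 0.05)$onset)
  }, logical(1))
  bound <- 1 - 0.95^k
  expect_lt(mean(hits), bound + 2 * sqrt(bound * (1 - bound) / 300))
})

test_that("shrinking alpha never gives an earlier onset", {
  withr::with_seed(6, {
    for (r in 1:20) {
      tc <- sim_tc(c(`0` = 0, `1` = runif(1, 0, 1), `2` = runif(1, 0, 2),
                     `3` = runif(1, 0, 3)), n = 8, seed = 600 + r)
      o1 <- recovery_onset(tc, alpha = 0.05)$onset
      o2 <- recovery_onset(tc, alpha = 0.005)$onset
      expect_true(is.na(o2) || (!is.na(o1) && o2 >= o1))
    }
  })
})

test_that("recovery onset validates its inputs", {
  tc <- sim_tc(c(`1` = 0, `2` = 1), seed = 7)
  expect_error(recovery_onset(tc), "0-hour")
  tc2 <- tibble::tibble(timepoint = c(0, 0, 1), enrichment = c(1, 2, 3))
  expect_error(recovery_onset(tc2), "at least 2 records")
})

test_that("Holm correction is available and more conservative", {
  tc <- sim_tc(c(`0` = 0, `1` = 0.9, `2` = 0.9, `3` = 5), n = 10, seed = 8)
  p_raw <- tidy(recovery_onset(tc))$p_adjusted
  p_holm <- tidy(recovery_onset(tc, p_adjust = "holm"))$p_adjusted
  expect_true(all(p_holm >= p_raw, na.rm = TRUE))
})

test_that("ORF translation-time arithmetic", {
  expect_equal(translation_time(3600)$minutes, 10)
  tt <- translation_time(aspm_orf_codons)
  expect_equal(tt$minutes, 3477 / 6 / 60)
  expect_equal(tt$minutes_rounded, 10)
  expect_equal(translation_time(3600, rate = 12)$minutes, 5)
  expect_error(translation_time(3600, rate = 0), "rate")
  expect_error(translation_time(0), "orf_codons")
})

test_that("the default washout pipeline recovers a 3-hour onset across replicates", {
  # 20 cells (40 centrosomes) per timepoint: sized so the 3 h effect has
  # ~99% power at the Holm-corrected level, making the replicate bound
  # informative about the pipeline rather than about sampling noise
  hits <- vapply(1:20, function(rep) {
    sims <- simulate_timecourse(scene_config(), washout_kinetics(),
                                n_cells_per_timepoint = 20,
                                seed = 4000 + rep)
    q <- suppressWarnings(
      quantify_timecourse(sims, channels = "rna", profile_channels = NULL,
                          seed = 4000 + rep))
    rr <- recovery_onset(q, channel = "rna", alpha = 0.05,
                         p_adjust = "holm")
    identical(rr$onset, 3)
  }, logical(1))
  expect_gte(sum(hits), 18)
})
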