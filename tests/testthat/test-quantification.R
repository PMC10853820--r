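px <- 0.1

test_that("enrichment vanishes on a uniform field", {
  img <- matrix(13.7, 120, 120)
  de <- disk_enrichment(img, c(6, 6), px, radius_um = 2, seed = 4)
  expect_equal(de$enrichment, 0)
})

test_that("an in-disk point source is recovered to 1%", {
  b <- 10; A <- 500; sigma <- 0.12
  dimpx <- c(200, 200)
  yy <- (seq_len(dimpx[1]) - 1) * px
  img <- matrix(b, dimpx[1], dimpx[2]) +
    A * exp(-outer((yy - 10)^2, (yy - 10)^2, `+`) / (2 * sigma^2))
  S <- A * 2 * pi * (sigma / px)^2
  de <- disk_enrichment(img, c(10, 10), px, radius_um = 2,
                        exclusion_centers = list(c(10, 10)), seed = 5)
  expect_lt(abs(de$enrichment - S) / S, 0.01)
})

test_that("disk membership equals brute-force pixel-centre enumeration", {
  img <- withr::with_seed(6, matrix(runif(90 * 110), 90, 110))
  for (ctr in list(c(4.5, 5.5), c(4.43, 6.07))) {
    de <- disk_enrichment(img, ctr, px, radius_um = 2, seed = 7)
    bf <- brute_force_disk(img, ctr, 2, px)
    expect_equal(de$n_pixels, bf$n_pixels)
    expect_equal(de$disk_total, bf$total)
  }
})

test_that("enrichment is exactly linear in image scale", {
  img <- withr::with_seed(8, matrix(rpois(100 * 100, 50), 100, 100))
  args <- list(center_um = c(5, 5), pixel_size = px, radius_um = 1.5,
               exclusion_centers = list(c(5, 5)), seed = 9)
  d1 <- do.call(disk_enrichment, c(list(img), args))
  d3 <- do.call(disk_enrichment, c(list(3 * img), args))
  expect_identical(d3$disk_total, 3 * d1$disk_total)
  expect_identical(d3$background_total, 3 * d1$background_total)
  expect_identical(d3$enrichment, 3 * d1$enrichment)
})

test_that("background placement respects exclusions or fails loudly", {
  img <- matrix(1, 60, 60)
  expect_error(
    disk_enrichment(img, c(3, 3), px, radius_um = 2,
                    cell_mask_mat = matrix(FALSE, 60, 60), seed = 1),
    "cell too small")
  # exclusion zone covering the whole image -> no valid placement
  expect_error(
    disk_enrichment(img, c(3, 3), px, radius_um = 2,
                    exclusion_centers = list(c(3, 3), c(0, 0), c(0, 5.9),
                                             c(5.9, 0), c(5.9, 5.9),
                                             c(3, 0), c(0, 3), c(5.9, 3),
                                             c(3, 5.9)),
                    seed = 1),
    "cell too small")
})

make_frame <- function(y, x, ay, ax, id = 1L)
  tibble::tibble(cell_id = "c", centrosome_id = id, y_um = y, x_um = x,
                 axis_y = ay, axis_x = ax)

test_that("line profiles self-centre on the marker peak", {
  sim <- simulate_cell(tiny_config(noise = FALSE, n_rna_free = 0), seed = 3)
  cc <- detect_centrosomes(sim$scene$channels$marker, px)
  fr <- build_frames(cc)
  prof <- line_profile(sim$scene$channels, fr[1, ], px, step = 0.05)
  expect_lte(abs(peak_position(prof, "marker")), 0.05 / 2)
})

test_that("a spindle-side protein blob is located at its true offset", {
  sim <- simulate_cell(tiny_config(noise = FALSE, n_rna_free = 0,
                                   protein_offset = -0.3), seed = 4)
  cc <- detect_centrosomes(sim$scene$channels$marker, px)
  fr <- build_frames(cc)
  for (i in 1:2) {
    prof <- line_profile(sim$scene$channels, fr[i, ], px)
    expect_lte(abs(peak_position(prof, "protein") - (-0.3)), 0.05)
  }
})

test_that("ties resolve to the smallest |position|, spindle side first", {
  grid <- seq(-1, 1, by = 0.05)
  flat <- tibble::tibble(position_um = grid, channel = "c",
                         value = rep(1, length(grid)))
  expect_equal(peak_position(flat, "c"), 0)
  rising <- tibble::tibble(position_um = grid, channel = "c",
                           value = seq_along(grid))
  expect_equal(peak_position(rising, "c"), 1)
  double <- tibble::tibble(position_um = grid, channel = "c",
                           value = ifelse(abs(abs(grid) - 0.4) < 1e-9,
                                          5, 1))
  expect_equal(peak_position(double, "c"), -0.4)
  allna <- tibble::tibble(position_um = grid, channel = "c",
                          value = NA_real_)
  expect_error(peak_position(allna, "c"), "all NA")
  expect_error(peak_position(flat, "missing"), "not present")
})

test_that("peak_position matches a brute-force scan on 200 random profiles", {
  withr::with_seed(10, {
    for (r in 1:200) {
      grid <- seq(-1, 1, by = 0.05)
      # coarse values induce frequent ties, exercising the tie rules
      vals <- sample(0:4, length(grid), replace = TRUE)
      prof <- tibble::tibble(position_um = grid, channel = "x",
                             value = as.numeric(vals))
      expect_identical(peak_position(prof, "x"),
                       brute_force_peak(grid, vals))
    }
  })
})

test_that("profiles that would leave the image raise a named error", {
  img <- matrix(1, 40, 40)
  chans <- list(marker = img)
  fr <- make_frame(0.2, 2, 1, 0, id = 9L)
  expect_error(line_profile(chans, fr, px, half_length = 1,
                            recenter = FALSE),
               "centrosome 9")
  # recentering search itself must stay in bounds too
  fr2 <- make_frame(2, 0.2, 0, 1, id = 4L)
  expect_error(line_profile(chans, fr2, px, half_length = 3), "centrosome 4")
})

test_that("quantify_scene returns one tidy row per centrosome and channel", {
  sim <- simulate_cell(tiny_config(), seed = 12)
  q <- quantify_scene(sim$scene, cell_id = "cellA", timepoint = 1.5,
                      seed = 2)
  expect_equal(nrow(q), 8)
  expect_setequal(unique(q$channel), c("marker", "rna", "protein", "dna"))
  expect_true(all(q$enrichment == q$disk_total - q$background_total))
  expect_true(all(abs(q$peak_position_um) <= 1))
  expect_equal(unique(q$timepoint), 1.5)
})
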