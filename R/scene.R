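#' Scene configuration for the synthetic metaphase-cell simulator
#'
#' Builds and validates the parameter set describing one simulated mitotic
#' cell: a circular cell containing two centrosomes that define the spindle
#' axis, a pericentrosomal ring of diffraction-limited RNA spots with a
#' tunable astral-side bias, freely diffusing cytoplasmic RNA spots, a
#' protein signal displaced along the spindle axis, a centrosome-marker
#' channel (pericentrin-like) and a DNA channel rendering the metaphase
#' plate.  Pixel values are photon counts: Poisson shot noise on
#' signal + background plus additive Gaussian read noise, clipped at zero.
#'
#' Distances are in micrometres, intensities in photons.  Images are 2-D,
#' the analogue of a maximum-intensity projection.
#'
#' @param image_shape integer (Y, X) image size in pixels.
#' @param pixel_size pixel pitch, um/pixel.
#' @param psf_sigma Gaussian PSF standard deviation, um; diffraction-limited
#'   spots and the centrosome marker are rendered at this width.
#' @param centrosome_separation pole-to-pole distance, um; must be smaller
#'   than the cell diameter.
#' @param cell_radius cell radius, um; the cell is centred in the image.
#' @param n_rna_centrosomal RNA spots ringing each centrosome.
#' @param n_rna_free RNA spots placed uniformly in the cell.
#' @param rna_ring_radius radius of the pericentrosomal RNA ring, um.
#' @param rna_astral_bias von Mises concentration kappa (>= 0) of ring-spot
#'   angles about the astral direction; 0 gives a uniform (unbiased) ring.
#' @param protein_offset signed displacement of the protein signal along the
#'   spindle axis, um; negative = spindle side, positive = astral side.
#' @param protein_sigma width of the protein blob, um.
#' @param channel_amplitudes named photon amplitudes (peak photons for
#'   point-like signals) for channels marker, rna, protein, dna.
#' @param background_level uniform background, photons/pixel.
#' @param read_noise_sd Gaussian read noise SD, photons.
#' @param stage_label mitotic stage annotation carried into the ground
#'   truth: one of "G2", "prometaphase", "metaphase".
#' @param noise logical; `FALSE` renders the noise-free expectation image
#'   (no Poisson, no read noise, background still added).
#' @param rna_amplitude_cv coefficient of variation of per-spot RNA
#'   amplitudes; 0 (default) renders every spot at the same amplitude.
#'
#' @return A validated list of class `scene_config`.
#' @export
scene_config <- function(image_shape = c(224L, 224L),
                         pixel_size = 0.1,
                         psf_sigma = 0.12,
                         centrosome_separation = 8,
                         cell_radius = 10,
                         n_rna_centrosomal = 8L,
                         n_rna_free = 40L,
                         rna_ring_radius = 0.5,
                         rna_astral_bias = 2,
                         protein_offset = -0.3,
                         protein_sigma = 0.3,
                         channel_amplitudes = c(marker = 800, rna = 50,
                                                protein = 150, dna = 30),
                         background_level = 100,
                         read_noise_sd = 2,
                         stage_label = "metaphase",
                         noise = TRUE,
                         rna_amplitude_cv = 0) {
  cfg <- list(
    image_shape = as.integer(image_shape),
    pixel_size = pixel_size,
    psf_sigma = psf_sigma,
    centrosome_separation = centrosome_separation,
    cell_radius = cell_radius,
    n_rna_centrosomal = as.integer(n_rna_centrosomal),
    n_rna_free = as.integer(n_rna_free),
    rna_ring_radius = rna_ring_radius,
    rna_astral_bias = rna_astral_bias,
    protein_offset = protein_offset,
    protein_sigma = protein_sigma,
    channel_amplitudes = channel_amplitudes,
    background_level = background_level,
    read_noise_sd = read_noise_sd,
    stage_label = stage_label,
    noise = isTRUE(noise),
    rna_amplitude_cv = rna_amplitude_cv
  )
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  fail <- function(field, msg) {
    stop("invalid scene configuration: field '", field, "' ", msg,
         call. = FALSE)
  }
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 8L))
    fail("image_shape", "must be two pixel counts >= 8")
  if (!is.numeric(cfg$pixel_size) || cfg$pixel_size <= 0)
    fail("pixel_size", "must be > 0")
  if (cfg$psf_sigma <= 0) fail("psf_sigma", "must be > 0")
  if (cfg$rna_ring_radius < 0) fail("rna_ring_radius", "must be >= 0")
  if (cfg$rna_astral_bias < 0) fail("rna_astral_bias", "must be >= 0 (kappa)")
  if (cfg$cell_radius <= 0) fail("cell_radius", "must be > 0")
  if (cfg$centrosome_separation <= 0 ||
      cfg$centrosome_separation >= 2 * cfg$cell_radius)
    fail("centrosome_separation", "must lie in (0, 2 * cell_radius)")
  if (cfg$n_rna_centrosomal < 0) fail("n_rna_centrosomal", "must be >= 0")
  if (cfg$n_rna_free < 0) fail("n_rna_free", "must be >= 0")
  if (cfg$protein_sigma <= 0) fail("protein_sigma", "must be > 0")
  need <- c("marker", "rna", "protein", "dna")
  if (!all(need %in% names(cfg$channel_amplitudes)))
    fail("channel_amplitudes", paste("must name", paste(need, collapse = ", ")))
  if (any(cfg$channel_amplitudes < 0))
    fail("channel_amplitudes", "must be non-negative")
  if (cfg$background_level < 0) fail("background_level", "must be >= 0")
  if (cfg$read_noise_sd < 0) fail("read_noise_sd", "must be >= 0")
  if (!cfg$stage_label %in% c("G2", "prometaphase", "metaphase"))
    fail("stage_label", "must be one of G2, prometaphase, metaphase")
  if (cfg$rna_amplitude_cv < 0) fail("rna_amplitude_cv", "must be >= 0")
  invisible(cfg)
}

#' Sample from the von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` reduces to the uniform
#' distribution on the circle.  Used for the angular placement of
#' pericentrosomal RNA spots about the astral direction.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration, >= 0.
#' @return numeric vector of angles in (-pi, pi] shifted to mu.
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) {
    theta <- stats::runif(n, -pi, pi)
  } else {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    theta <- numeric(0)
    while (length(theta) < n) {
      m <- max(16L, ceiling((n - length(theta)) * 1.6))
      u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
      theta <- c(theta, (sign(u3 - 0.5) * acos(f))[ok])
    }
    theta <- theta[seq_len(n)]
  }
  atan2(sin(theta + mu), cos(theta + mu))
}

# Render an isotropic Gaussian of peak amplitude `amp` (photons) at
# (y_um, x_um) into image matrix `img`, evaluated at pixel centres within
# a 5-sigma window.  Physical position of pixel [i, j] (1-based) is
# ((i - 1) * px, (j - 1) * px).
add_gaussian <- function(img, y_um, x_um, amp, sigma_um, pixel_size,
                         sigma_y_um = sigma_um, axis_angle = 0) {
  ny <- nrow(img); nx <- ncol(img)
  r_px <- ceiling(5 * max(sigma_um, sigma_y_um) / pixel_size)
  cy <- y_um / pixel_size; cx <- x_um / pixel_size
  i0 <- max(0L, floor(cy) - r_px); i1 <- min(ny - 1L, ceiling(cy) + r_px)
  j0 <- max(0L, floor(cx) - r_px); j1 <- min(nx - 1L, ceiling(cx) + r_px)
  if (i0 > i1 || j0 > j1) return(img)
  yy <- (i0:i1) * pixel_size - y_um
  xx <- (j0:j1) * pixel_size - x_um
  # rotate into (along-axis, perpendicular) coordinates for anisotropic blobs
  ca <- cos(axis_angle); sa <- sin(axis_angle)
  u <- outer(yy * sa, xx * ca, `+`)      # along-axis coordinate
  v <- outer(yy * ca, xx * -sa, `+`)     # perpendicular coordinate
  g <- amp * exp(-(u^2 / (2 * sigma_um^2) + v^2 / (2 * sigma_y_um^2)))
  img[(i0:i1) + 1L, (j0:j1) + 1L] <- img[(i0:i1) + 1L, (j0:j1) + 1L] + g
  img
}

#' Simulate one mitotic cell
#'
#' Renders a four-channel image (marker, rna, protein, dna) of a metaphase
#' cell and returns it together with the exact ground truth used to render
#' it.  RNA ring-spot angles about each centrosome follow a von Mises law
#' centred on that centrosome's astral direction with concentration
#' `rna_astral_bias`; the protein channel is a Gaussian blob displaced by
#' `protein_offset` along the signed spindle axis (negative = spindle side);
#' every pixel is Poisson(signal + background) + N(0, read_noise_sd),
#' clipped at zero.  Identical `(config, seed)` gives identical output.
#'
#' @param config a [scene_config()].
#' @param seed integer seed; all randomness is derived from it.
#' @return list with elements `scene` (class `scene`: named channel
#'   matrices, pixel size, cell geometry, stage label) and `truth` (class
#'   `ground_truth`: centrosome centres, signed astral unit axes, RNA spot
#'   table, true protein offset, stage label).
#' @export
#' @examples
#' sim <- simulate_cell(scene_config(image_shape = c(96, 96),
#'                                   cell_radius = 4,
#'                                   centrosome_separation = 3), seed = 1)
#' dim(sim$scene$channels$rna)
simulate_cell <- function(config, seed) {
  validate_scene_config(config)
  withr::with_seed(as.integer(seed), simulate_cell_impl(config))
}

simulate_cell_impl <- function(cfg) {
  ny <- cfg$image_shape[1]; nx <- cfg$image_shape[2]
  px <- cfg$pixel_size
  centre <- c((ny - 1) / 2, (nx - 1) / 2) * px   # (y, x) um, image centre
  half <- cfg$centrosome_separation / 2
  # poles along the x axis; astral direction points away from the midpoint
  centers <- rbind(c(centre[1], centre[2] - half),
                   c(centre[1], centre[2] + half))
  axes <- rbind(c(0, -1), c(0, 1))
  amp <- cfg$channel_amplitudes

  rna <- list()
  for (k in 1:2) {
    n <- cfg$n_rna_centrosomal
    if (n > 0) {
      mu <- atan2(axes[k, 1], axes[k, 2])
      th <- rvonmises(n, mu = mu, kappa = cfg$rna_astral_bias)
      rna[[length(rna) + 1L]] <- tibble::tibble(
        type = "centrosomal", centrosome_id = k,
        y_um = centers[k, 1] + cfg$rna_ring_radius * sin(th),
        x_um = centers[k, 2] + cfg$rna_ring_radius * cos(th))
    }
  }
  if (cfg$n_rna_free > 0) {
    r <- cfg$cell_radius * sqrt(stats::runif(cfg$n_rna_free))
    phi <- stats::runif(cfg$n_rna_free, -pi, pi)
    rna[[length(rna) + 1L]] <- tibble::tibble(
      type = "free", centrosome_id = NA_integer_,
      y_um = centre[1] + r * sin(phi),
      x_um = centre[2] + r * cos(phi))
  }
  rna <- if (length(rna)) dplyr::bind_rows(rna) else
    tibble::tibble(type = character(), centrosome_id = integer(),
                   y_um = numeric(), x_um = numeric())

  blank <- matrix(0, ny, nx)
  marker <- blank; rna_ch <- blank; protein <- blank; dna <- blank
  for (k in 1:2) {
    marker <- add_gaussian(marker, centers[k, 1], centers[k, 2],
                           amp[["marker"]], cfg$psf_sigma, px)
    pc <- centers[k, ] + cfg$protein_offset * axes[k, ]
    protein <- add_gaussian(protein, pc[1], pc[2], amp[["protein"]],
                            cfg$protein_sigma, px)
  }
  if (nrow(rna) > 0) {
    a <- rep(amp[["rna"]], nrow(rna))
    if (cfg$rna_amplitude_cv > 0)
      a <- a * pmax(0, stats::rnorm(nrow(rna), 1, cfg$rna_amplitude_cv))
    for (i in seq_len(nrow(rna)))
      rna_ch <- add_gaussian(rna_ch, rna$y_um[i], rna$x_um[i],
                             a[i], cfg$psf_sigma, px)
  }
  if (amp[["dna"]] > 0) {
    if (cfg$stage_label == "metaphase") {
      # metaphase plate: narrow along the spindle axis, wide across it
      dna <- add_gaussian(dna, centre[1], centre[2], amp[["dna"]],
                          sigma_um = 0.4, pixel_size = px,
                          sigma_y_um = min(3, cfg$cell_radius / 2),
                          axis_angle = 0)
    } else {
      dna <- add_gaussian(dna, centre[1], centre[2], amp[["dna"]],
                          sigma_um = min(2.5, cfg$cell_radius / 2),
                          pixel_size = px)
    }
  }

  channels <- list(marker = marker, rna = rna_ch,
                   protein = protein, dna = dna)
  channels <- lapply(channels, function(m) {
    e <- m + cfg$background_level
    if (!cfg$noise) return(e)
    n <- length(e)
    noisy <- stats::rpois(n, lambda = e) +
      stats::rnorm(n, 0, cfg$read_noise_sd)
    matrix(pmax(noisy, 0), ny, nx)
  })

  scene <- structure(list(
    channels = channels,
    pixel_size = px,
    cell_center_um = centre,
    cell_radius_um = cfg$cell_radius,
    stage_label = cfg$stage_label
  ), class = "scene")

  truth <- structure(list(
    centrosome_centers = centers,
    spindle_axes = axes,
    rna_positions = rna,
    protein_offset_true = cfg$protein_offset,
    stage_label = cfg$stage_label
  ), class = "ground_truth")

  list(scene = scene, truth = truth)
}

#' Binary mask of pixels inside the simulated cell
#'
#' @param scene a `scene` from [simulate_cell()].
#' @return logical matrix, TRUE where the pixel centre lies within the
#'   cell radius of the cell centre.
#' @export
cell_mask <- function(scene) {
  dm <- dim(scene$channels[[1]])
  px <- scene$pixel_size
  yy <- (seq_len(dm[1]) - 1) * px - scene$cell_center_um[1]
  xx <- (seq_len(dm[2]) - 1) * px - scene$cell_center_um[2]
  outer(yy^2, xx^2, `+`) <= scene$cell_radius_um^2
}

#' Washout recovery kinetics
#'
#' Piecewise-linear model of centrosomal RNA recovery after removal of a
#' translation inhibitor: no centrosomal RNA before and at `lag`, then a
#' linear rise reaching `recover_fraction` of the untreated centrosomal
#' count at `end_time`.  The default grid matches a standard puromycin
#' washout fixation series (0, 10, 45 min, then hourly to 4 h), and the
#' default kinetics place the onset of recovery after the 2-hour fixation
#' so that centrosomal RNA is first present at the 3-hour timepoint; the
#' default `recover_fraction` of 0.6 leaves the final timepoint below the
#' untreated baseline.
#'
#' @param lag hours before any centrosomal RNA reappears.
#' @param recover_fraction fraction of the untreated centrosomal RNA count
#'   reached at `end_time`, in \[0, 1\].
#' @param end_time hours, end of the ramp.
#' @param timepoints ascending fixation times in hours, first must be 0.
#' @return list of class `washout_kinetics`.
#' @export
washout_kinetics <- function(lag = 2,
                             recover_fraction = 0.6,
                             end_time = 4,
                             timepoints = c(0, 10 / 60, 45 / 60, 1, 2, 3, 4)) {
  if (recover_fraction < 0 || recover_fraction > 1)
    stop("recover_fraction must lie in [0, 1]", call. = FALSE)
  if (lag > end_time) stop("lag must be <= end_time", call. = FALSE)
  if (is.unsorted(timepoints, strictly = TRUE) || timepoints[1] != 0)
    stop("timepoints must be strictly ascending and start at 0",
         call. = FALSE)
  structure(list(lag = lag, recover_fraction = recover_fraction,
                 end_time = end_time, timepoints = timepoints),
            class = "washout_kinetics")
}

#' Recovery fraction r(t) of the washout ramp
#'
#' r(t) = 0 for t <= lag, rises linearly from 0 at `lag` to
#' `recover_fraction` at `end_time`, and stays there afterwards.
#'
#' @param kinetics a [washout_kinetics()].
#' @param t hours (vectorised).
#' @return numeric vector of fractions in \[0, recover_fraction\].
#' @export
recovery_fraction <- function(kinetics, t) {
  r <- ifelse(t <= kinetics$lag, 0,
              kinetics$recover_fraction *
                pmin(1, (t - kinetics$lag) /
                       (kinetics$end_time - kinetics$lag)))
  pmax(0, r)
}

#' Simulate a washout time-course
#'
#' Generates `n_cells_per_timepoint` cells at each kinetics timepoint.  The
#' centrosomal RNA count per centrosome at time t is
#' `round(n_rna_centrosomal * r(t))` with r(t) from [recovery_fraction()];
#' the free RNA count is constant.  Deterministic for a given seed.
#'
#' @param config a [scene_config()] describing the untreated cell.
#' @param kinetics a [washout_kinetics()].
#' @param n_cells_per_timepoint cells per fixation time, >= 1.
#' @param seed integer master seed.
#' @return tibble with columns `timepoint` (hours), `cell_id`, `scene`
#'   (list), `truth` (list).
#' @export
simulate_timecourse <- function(config, kinetics, n_cells_per_timepoint,
                                seed) {
  validate_scene_config(config)
  if (!inherits(kinetics, "washout_kinetics"))
    stop("kinetics must be a washout_kinetics object", call. = FALSE)
  if (n_cells_per_timepoint < 1)
    stop("n_cells_per_timepoint must be >= 1", call. = FALSE)
  grid <- tidyr::expand_grid(timepoint = kinetics$timepoints,
                             cell = seq_len(n_cells_per_timepoint))
  cell_seeds <- withr::with_seed(as.integer(seed),
    sample.int(.Machine$integer.max, nrow(grid)))
  rows <- purrr::pmap(list(grid$timepoint, grid$cell, cell_seeds),
    function(t, cell, s) {
      cfg_t <- config
      cfg_t$n_rna_centrosomal <-
        as.integer(round(config$n_rna_centrosomal *
                           recovery_fraction(kinetics, t)))
      sim <- simulate_cell(cfg_t, seed = s)
      tibble::tibble(timepoint = t,
                     cell_id = sprintf("t%g_c%02d", t, cell),
                     scene = list(sim$scene), truth = list(sim$truth))
    })
  dplyr::bind_rows(rows)
}

#' @export
print.scene <- function(x, ...) {
  dm <- dim(x$channels[[1]])
  cat(sprintf(
    "<scene> %d x %d px (%.3g um/px), channels: %s, stage: %s\n",
    dm[1], dm[2], x$pixel_size,
    paste(names(x$channels), collapse = ", "), x$stage_label))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> 2 centrosomes, %d RNA spots, protein offset %.2f um, stage %s\n",
    nrow(x$rna_positions), x$protein_offset_true, x$stage_label))
  invisible(x)
}
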