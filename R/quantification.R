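# Logical mask of pixels whose centres lie within radius_um of a physical
# (y_um, x_um) point.  Pixel [i, j] (1-based) has centre
# ((i - 1) * px, (j - 1) * px).  Distances are compared in pixel units
# with a 1e-9 slack so that boundary pixels (distance exactly equal to the
# radius) are included consistently for every grid-aligned placement.
disk_mask <- function(dim_px, center_um, radius_um, pixel_size) {
  yy <- ((seq_len(dim_px[1]) - 1) - center_um[1] / pixel_size)^2
  xx <- ((seq_len(dim_px[2]) - 1) - center_um[2] / pixel_size)^2
  outer(yy, xx, `+`) <= (radius_um / pixel_size)^2 + 1e-9
}

#' Disk-ROI enrichment with in-cell background subtraction
#'
#' Total intensity in a circular ROI of radius `radius_um` around a
#' centrosome, minus a matched in-cell background: the median of the same
#' disk sum over `n_background` seeded random placements inside
#' `cell_mask_mat`, each at least `2 * radius_um` from every exclusion
#' centre and with the disk fully inside the image.  Enrichment is exactly
#' `disk_total - background_total` and may be negative.
#'
#' @param image numeric matrix, one channel (photons).
#' @param center_um (y, x) ROI centre, um.
#' @param pixel_size um/pixel.
#' @param radius_um ROI radius (default 2 um).
#' @param cell_mask_mat logical matrix of in-cell pixels; `NULL` means the
#'   whole image.
#' @param exclusion_centers list (or 2-column matrix) of (y, x) um points
#'   that background placements must avoid — normally both centrosomes.
#' @param seed integer seed for the background placements.
#' @param n_background number of random background disks (default 10).
#' @param max_tries attempts before giving up on placement.
#' @return one-row tibble: `disk_total`, `background_total`, `enrichment`,
#'   `n_pixels`.
#' @export
disk_enrichment <- function(image, center_um, pixel_size, radius_um = 2,
                            cell_mask_mat = NULL, exclusion_centers = NULL,
                            seed = 1L, n_background = 10L,
                            max_tries = 1000L) {
  stopifnot(radius_um > 0, pixel_size > 0)
  dm <- dim(image)
  ylim <- (dm[1] - 1) * pixel_size
  xlim <- (dm[2] - 1) * pixel_size
  if (center_um[1] < 0 || center_um[1] > ylim ||
      center_um[2] < 0 || center_um[2] > xlim)
    stop("ROI center lies outside the image", call. = FALSE)
  if (is.null(cell_mask_mat)) cell_mask_mat <- matrix(TRUE, dm[1], dm[2])
  excl <- if (is.null(exclusion_centers)) matrix(numeric(0), 0, 2)
          else do.call(rbind, lapply(
            if (is.matrix(exclusion_centers))
              split(exclusion_centers, row(exclusion_centers)[, 1])
            else exclusion_centers, as.numeric))

  disk_total <- sum(image[disk_mask(dm, center_um, radius_um, pixel_size)])

  inside <- which(cell_mask_mat, arr.ind = TRUE)
  if (nrow(inside) == 0)
    stop("cell too small for background ROI", call. = FALSE)
  bg_sums <- withr::with_seed(as.integer(seed), {
    sums <- numeric(0)
    tries <- 0L
    while (length(sums) < n_background && tries < max_tries) {
      tries <- tries + 1L
      p <- inside[sample.int(nrow(inside), 1L), ]
      c_um <- (p - 1) * pixel_size
      if (c_um[1] < radius_um || c_um[1] > ylim - radius_um ||
          c_um[2] < radius_um || c_um[2] > xlim - radius_um) next
      if (nrow(excl) > 0 &&
          any(sqrt((excl[, 1] - c_um[1])^2 + (excl[, 2] - c_um[2])^2) <
                2 * radius_um)) next
      sums <- c(sums, sum(image[disk_mask(dm, c_um, radius_um, pixel_size)]))
    }
    if (length(sums) < n_background)
      stop("cell too small for background ROI", call. = FALSE)
    sums
  })
  background_total <- stats::median(bg_sums)
  tibble::tibble(disk_total = disk_total,
                 background_total = background_total,
                 enrichment = disk_total - background_total,
                 n_pixels = sum(disk_mask(dm, center_um, radius_um,
                                          pixel_size)))
}

# Bilinear interpolation of matrix values at physical (y_um, x_um) points.
interp_bilinear <- function(image, y_um, x_um, pixel_size) {
  pracma::interp2(x = (seq_len(ncol(image)) - 1) * pixel_size,
                  y = (seq_len(nrow(image)) - 1) * pixel_size,
                  Z = image, xp = x_um, yp = y_um, method = "linear")
}

# Tie-breaking argmax on a signed-position grid: maximum value, ties broken
# by smallest |position|, then by the spindle (negative) side.
argmax_signed <- function(positions, values) {
  mx <- max(values)
  tied <- which(values >= mx - 1e-12 * max(1, abs(mx)))
  pos <- positions[tied]
  pos <- pos[order(abs(pos), pos)]
  pos[1]
}

#' Signed line profile through a centrosome
#'
#' Samples every channel by bilinear interpolation along the spindle-to-
#' astral axis of a centrosome frame, at signed positions from `-half_length`
#' to `+half_length` in steps of `step` (negative = spindle side).  Before
#' sampling, the centre is re-refined to the peak of the marker channel
#' along the axis (searched within `recenter_range` um of the nominal
#' centre), so position 0 sits on the peak marker signal.
#'
#' @param channels named list of channel matrices (must include `marker`
#'   unless `recenter = FALSE`).
#' @param frame one row of [build_frames()].
#' @param pixel_size um/pixel.
#' @param half_length profile half-length L, um (default 1).
#' @param step sampling step, um (default 0.05).
#' @param recenter logical; re-centre on the marker peak first.
#' @param recenter_range search half-range for the marker peak, um.
#' @param marker name of the marker channel.
#' @return tibble of class `line_profile` with columns `position_um`,
#'   `channel`, `value`; attributes `center_um`, `axis`, `centrosome_id`.
#' @export
line_profile <- function(channels, frame, pixel_size, half_length = 1,
                         step = 0.05, recenter = TRUE,
                         recenter_range = 0.5, marker = "marker") {
  stopifnot(half_length > 0, step > 0)
  center <- c(frame$y_um, frame$x_um)
  axis <- c(frame$axis_y, frame$axis_x)
  id <- if ("centrosome_id" %in% names(frame)) frame$centrosome_id else NA
  dm <- dim(channels[[1]])
  check_bounds <- function(y, x) {
    if (any(y < 0 | y > (dm[1] - 1) * pixel_size |
            x < 0 | x > (dm[2] - 1) * pixel_size))
      stop(sprintf("line profile leaves image bounds at centrosome %s",
                   as.character(id)), call. = FALSE)
  }
  if (recenter) {
    if (!marker %in% names(channels))
      stop("recentering requires a '", marker, "' channel", call. = FALSE)
    tt <- seq(-recenter_range, recenter_range, by = step / 5)
    yy <- center[1] + tt * axis[1]; xx <- center[2] + tt * axis[2]
    check_bounds(yy, xx)
    mv <- interp_bilinear(channels[[marker]], yy, xx, pixel_size)
    tstar <- argmax_signed(tt, mv)
    center <- center + tstar * axis
  }
  tgrid <- seq(-half_length, half_length, by = step)
  yy <- center[1] + tgrid * axis[1]; xx <- center[2] + tgrid * axis[2]
  check_bounds(yy, xx)
  prof <- purrr::map_dfr(names(channels), function(ch) {
    tibble::tibble(position_um = tgrid, channel = ch,
                   value = interp_bilinear(channels[[ch]], yy, xx,
                                           pixel_size))
  })
  structure(prof, class = c("line_profile", class(prof)),
            center_um = center, axis = axis, centrosome_id = id)
}

#' Signed peak position of a channel along a line profile
#'
#' Position of the maximum interpolated intensity; ties are broken by the
#' smallest absolute position, then by the spindle (negative) side, so a
#' constant channel returns 0.
#'
#' @param profile a [line_profile()].
#' @param channel channel name.
#' @return signed position in um (negative = spindle side).
#' @export
peak_position <- function(profile, channel) {
  sub <- profile[profile$channel == channel, ]
  if (nrow(sub) == 0)
    stop("channel '", channel, "' not present in profile", call. = FALSE)
  if (all(is.na(sub$value)))
    stop("channel '", channel, "' is all NA", call. = FALSE)
  ok <- !is.na(sub$value)
  argmax_signed(sub$position_um[ok], sub$value[ok])
}

#' Quantify one scene: disk enrichment and peak positions per centrosome
#'
#' Runs the full measurement chain on a single image: detect the two
#' centrosomes in the marker channel, build signed spindle-to-astral
#' frames, measure per-channel disk enrichment (background-subtracted) and
#' per-channel line-profile peak positions.
#'
#' @param scene a `scene` (or a named list of channel matrices plus
#'   `pixel_size`, `cell_center_um`, `cell_radius_um`).
#' @param cell_id identifier for the output rows.
#' @param timepoint optional hours, carried into the output.
#' @param radius_um disk-ROI radius (default 2 um).
#' @param half_length_um profile half-length (default 1 um).
#' @param step_um profile step (default 0.05 um).
#' @param channels channels to quantify (default all).
#' @param profile_channels channels for which peak positions are measured
#'   (default the quantified channels); `NULL` skips profiles.
#' @param seed seed for background-ROI placement.
#' @param min_separation,psf_sigma detection parameters passed through.
#' @return tibble, one row per centrosome x channel: `cell_id`,
#'   `centrosome_id`, `timepoint`, `stage`, `channel`, `disk_total`,
#'   `background_total`, `enrichment`, `peak_position_um`.
#' @export
quantify_scene <- function(scene, cell_id = "cell1", timepoint = NA_real_,
                           radius_um = 2, half_length_um = 1,
                           step_um = 0.05,
                           channels = names(scene$channels),
                           profile_channels = channels,
                           seed = 1L, min_separation = 2,
                           psf_sigma = 0.12) {
  px <- scene$pixel_size
  centers <- detect_centrosomes(scene$channels$marker, px,
                                expected_n = 2L,
                                min_separation = min_separation)
  frames <- build_frames(centers, cell_id = cell_id)
  mask <- cell_mask(scene)
  excl <- lapply(1:2, function(i) c(frames$y_um[i], frames$x_um[i]))
  purrr::map_dfr(1:2, function(i) {
    fr <- frames[i, ]
    prof <- if (!is.null(profile_channels))
      line_profile(scene$channels, fr, px, half_length = half_length_um,
                   step = step_um)
    purrr::map_dfr(channels, function(ch) {
      de <- disk_enrichment(scene$channels[[ch]],
                            c(fr$y_um, fr$x_um), px,
                            radius_um = radius_um,
                            cell_mask_mat = mask,
                            exclusion_centers = excl,
                            seed = seed + 131L * i)
      tibble::tibble(
        cell_id = cell_id, centrosome_id = i, timepoint = timepoint,
        stage = scene$stage_label, channel = ch,
        disk_total = de$disk_total,
        background_total = de$background_total,
        enrichment = de$enrichment,
        peak_position_um = if (!is.null(profile_channels) &&
                               ch %in% profile_channels)
          peak_position(prof, ch) else NA_real_)
    })
  })
}

#' Quantify every cell of a simulated time-course
#'
#' @param sims tibble from [simulate_timecourse()].
#' @param ... passed to [quantify_scene()].
#' @param seed base seed for background-ROI placement; each cell gets a
#'   distinct derived seed.
#' @return bound tibble of [quantify_scene()] rows; cells whose centrosome
#'   pair cannot be detected are skipped with a warning.
#' @export
quantify_timecourse <- function(sims, ..., seed = 1L) {
  dots <- list(...)
  purrr::map_dfr(seq_len(nrow(sims)), function(i) {
    args <- c(list(sims$scene[[i]], cell_id = sims$cell_id[i],
                   timepoint = sims$timepoint[i],
                   seed = seed + 977L * i), dots)
    res <- tryCatch(
      do.call(quantify_scene, args),
      error = function(e) {
        warning(sprintf("cell %s skipped: %s", sims$cell_id[i],
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    res
  })
}
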