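# Strict local maxima of a matrix against its 8 neighbours, computed with
# toroidal (circular) shifts so detection commutes exactly with circular
# image translation.
local_maxima <- function(m) {
  shift2 <- function(m, dy, dx) {
    ny <- nrow(m); nx <- ncol(m)
    m[((seq_len(ny) - 1 - dy) %% ny) + 1, ((seq_len(nx) - 1 - dx) %% nx) + 1]
  }
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- out & (m > shift2(m, dy, dx))
  }
  out
}

# Gaussian smoothing by FFT convolution with circular boundary.
gauss_smooth <- function(m, sigma_px) {
  r <- max(1L, ceiling(4 * sigma_px))
  x <- -r:r
  k1 <- exp(-x^2 / (2 * sigma_px^2))
  k <- outer(k1, k1)
  k <- k / sum(k)
  EBImage::filter2(m, k, boundary = "circular")
}

# Laplacian-of-Gaussian blob response, scale-normalised and sign-flipped so
# bright blobs of radius ~ sigma give positive peaks.  The kernel is made
# zero-sum so a constant background contributes nothing.
log_response <- function(m, sigma_px) {
  r <- max(2L, ceiling(4 * sigma_px))
  x <- -r:r
  g <- exp(-outer(x^2, x^2, `+`) / (2 * sigma_px^2))
  rr <- outer(x^2, x^2, `+`)
  k <- -(rr - 2 * sigma_px^2) / sigma_px^2 * g   # -sigma^2 * LoG, unnormalised
  k <- k - mean(k)
  k <- k / sum(k[k > 0])
  EBImage::filter2(m, k, boundary = "circular")
}

# Intensity-weighted centroid refinement in a 3x3 window around 1-based
# peak indices (iy, ix) of matrix m; returns 0-based subpixel (y, x).
refine_centroid <- function(m, iy, ix) {
  ny <- nrow(m); nx <- ncol(m)
  ys <- pmin(pmax(iy + (-1:1), 1L), ny)
  xs <- pmin(pmax(ix + (-1:1), 1L), nx)
  w <- m[ys, xs, drop = FALSE]
  w <- w - min(w)
  if (sum(w) <= 0) return(c(iy - 1, ix - 1))
  c(sum((ys - 1) * rowSums(w)) / sum(w),
    sum((xs - 1) * colSums(w)) / sum(w))
}

#' Detect centrosomes in a marker channel
#'
#' Finds up to `expected_n` local maxima of the Gaussian-smoothed marker
#' channel that rise above the image background (median + k * MAD of the
#' smoothed image), enforces a minimum mutual separation greedily in order
#' of descending peak intensity, and refines each centre to subpixel
#' precision by an intensity-weighted centroid in a 3x3 window.
#'
#' If fewer than `expected_n` maxima survive, the result carries
#' `attr(, "incomplete") = TRUE` and a warning is raised.
#'
#' @param marker_channel numeric matrix (photons).
#' @param pixel_size um/pixel.
#' @param expected_n number of centrosomes sought (2 for metaphase).
#' @param min_separation minimum centre-to-centre distance, um.
#' @param smooth_sigma smoothing scale, um.
#' @param k MAD multiplier of the background threshold.
#' @return tibble with columns `centrosome_id`, `y_um`, `x_um`, `peak`
#'   (smoothed peak intensity), ordered by descending peak.
#' @export
detect_centrosomes <- function(marker_channel, pixel_size,
                               expected_n = 2L, min_separation = 2,
                               smooth_sigma = 0.2, k = 5) {
  stopifnot(expected_n >= 1, pixel_size > 0)
  empty <- tibble::tibble(centrosome_id = integer(), y_um = numeric(),
                          x_um = numeric(), peak = numeric())
  if (length(marker_channel) == 0) return(empty)
  sm <- gauss_smooth(marker_channel, smooth_sigma / pixel_size)
  thr <- stats::median(sm) + k * stats::mad(sm)
  cand <- which(local_maxima(sm) & sm > thr, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    warning("no centrosome candidates above background", call. = FALSE)
    attr(empty, "incomplete") <- TRUE
    return(empty)
  }
  ord <- order(sm[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- matrix(numeric(0), 0, 2)
  peaks <- numeric(0)
  min_sep_px <- min_separation / pixel_size
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(keep) > 0 &&
        any(sqrt((keep[, 1] - p[1])^2 + (keep[, 2] - p[2])^2) < min_sep_px))
      next
    keep <- rbind(keep, p)
    peaks <- c(peaks, sm[p[1], p[2]])
    if (nrow(keep) == expected_n) break
  }
  ref <- t(apply(keep, 1, function(p) refine_centroid(sm, p[1], p[2])))
  out <- tibble::tibble(centrosome_id = seq_len(nrow(keep)),
                        y_um = ref[, 1] * pixel_size,
                        x_um = ref[, 2] * pixel_size,
                        peak = peaks)
  if (nrow(out) < expected_n) {
    warning(sprintf("found %d of %d expected centrosomes", nrow(out),
                    expected_n), call. = FALSE)
    attr(out, "incomplete") <- TRUE
  }
  out
}

#' Build signed spindle-to-astral frames from a centrosome pair
#'
#' For a metaphase cell the two centrosomes sit at opposite spindle poles;
#' each centrosome's frame axis is the unit vector from its partner through
#' itself, i.e. pointing away from the metaphase plate.  Signed positions
#' along the axis are negative on the spindle side and positive on the
#' astral side.
#'
#' @param centers tibble with columns `y_um`, `x_um` (exactly two rows).
#' @param cell_id identifier carried into the frames.
#' @return tibble with one row per centrosome: `cell_id`, `centrosome_id`,
#'   `y_um`, `x_um`, `partner_y_um`, `partner_x_um`, `axis_y`, `axis_x`.
#' @export
build_frames <- function(centers, cell_id = "cell1") {
  if (nrow(centers) != 2L)
    stop(sprintf("cell '%s': need exactly 2 centrosome centers, got %d",
                 cell_id, nrow(centers)), call. = FALSE)
  purrr::map_dfr(1:2, function(i) {
    j <- 3L - i
    d <- c(centers$y_um[i] - centers$y_um[j],
           centers$x_um[i] - centers$x_um[j])
    d <- d / sqrt(sum(d^2))
    tibble::tibble(cell_id = cell_id, centrosome_id = i,
                   y_um = centers$y_um[i], x_um = centers$x_um[i],
                   partner_y_um = centers$y_um[j],
                   partner_x_um = centers$x_um[j],
                   axis_y = d[1], axis_x = d[2])
  })
}

#' Detect diffraction-limited smFISH spots
#'
#' Computes a scale-normalised Laplacian-of-Gaussian response at the PSF
#' scale, keeps strict local maxima whose response exceeds
#' median + k * MAD of the response image, and refines each detection by
#' an intensity-weighted centroid in a 3x3 window of the response.
#'
#' @param rna_channel numeric matrix (photons).
#' @param pixel_size um/pixel.
#' @param psf_sigma expected spot width, um.
#' @param k MAD threshold multiplier (default 5).
#' @return tibble of spots sorted by descending `score` (LoG response)
#'   with columns `spot_id`, `y_um`, `x_um`, `intensity` (median-subtracted
#'   peak photons), `score`.
#' @export
detect_spots <- function(rna_channel, pixel_size, psf_sigma = 0.12, k = 5) {
  stopifnot(psf_sigma > 0, k > 0, pixel_size > 0)
  resp <- log_response(rna_channel, psf_sigma / pixel_size)
  thr <- stats::median(resp) + k * stats::mad(resp)
  cand <- which(local_maxima(resp) & resp > thr, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(tibble::tibble(spot_id = integer(), y_um = numeric(),
                          x_um = numeric(), intensity = numeric(),
                          score = numeric()))
  scores <- resp[cand]
  bg <- stats::median(rna_channel)
  ref <- t(apply(cand, 1, function(p) refine_centroid(resp, p[1], p[2])))
  out <- tibble::tibble(y_um = ref[, 1] * pixel_size,
                        x_um = ref[, 2] * pixel_size,
                        intensity = rna_channel[cand] - bg,
                        score = scores)
  out <- dplyr::arrange(out, dplyr::desc(.data$score))
  dplyr::mutate(out, spot_id = dplyr::row_number(),
                .before = "y_um")
}
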