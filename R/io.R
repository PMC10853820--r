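#' Write a scene to disk as TIFF plus a metadata sidecar
#'
#' The four channels are stored as pages of a 16-bit TIFF (photon values
#' divided by a per-file intensity scale), and acquisition metadata —
#' pixel size, channel names, intensity scale, stage label, cell geometry,
#' optional timepoint and cell id — goes to a JSON sidecar next to the
#' image.  The ground truth, when given, is written as a CSV with one row
#' per object.
#'
#' @param scene a `scene` from [simulate_cell()].
#' @param path output TIFF path (`.tif`); the sidecar is `<path>.json` and
#'   the truth table `<path stem>_truth.csv`.
#' @param truth optional `ground_truth` to serialise.
#' @param timepoint,cell_id optional annotations stored in the sidecar.
#' @return invisibly, the TIFF path.
#' @export
write_scene <- function(scene, path, truth = NULL, timepoint = NA_real_,
                        cell_id = NA_character_) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  scale <- max(1, max(vapply(scene$channels, max, numeric(1))))
  pages <- lapply(scene$channels, function(m) pmin(m / scale, 1))
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 16L,
                  compression = "deflate", reduce = FALSE)
  meta <- list(pixel_size_um = scene$pixel_size,
               channels = names(scene$channels),
               intensity_scale = scale,
               stage_label = scene$stage_label,
               cell_center_um = as.numeric(scene$cell_center_um),
               cell_radius_um = scene$cell_radius_um,
               timepoint = timepoint, cell_id = cell_id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(truth)) {
    tt <- truth_table(truth, timepoint = timepoint, cell_id = cell_id)
    utils::write.csv(tt, sub("\\.tiff?$", "_truth.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Flatten a ground truth to a tidy object table
#'
#' @param truth a `ground_truth`.
#' @param timepoint,cell_id annotations repeated on every row.
#' @return tibble, one row per object: `type` (centrosome /
#'   rna_centrosomal / rna_free), `y_um`, `x_um`, `axis_y`, `axis_x`,
#'   `centrosome_id`, `timepoint`, `cell_id`, `stage`.
#' @export
truth_table <- function(truth, timepoint = NA_real_,
                        cell_id = NA_character_) {
  cs <- tibble::tibble(type = "centrosome",
                       y_um = truth$centrosome_centers[, 1],
                       x_um = truth$centrosome_centers[, 2],
                       axis_y = truth$spindle_axes[, 1],
                       axis_x = truth$spindle_axes[, 2],
                       centrosome_id = 1:2)
  rna <- dplyr::mutate(truth$rna_positions,
                       type = paste0("rna_", .data$type),
                       axis_y = NA_real_, axis_x = NA_real_)
  dplyr::bind_rows(cs, rna[, c("type", "y_um", "x_um", "axis_y",
                               "axis_x", "centrosome_id")]) |>
    dplyr::mutate(timepoint = timepoint, cell_id = cell_id,
                  stage = truth$stage_label)
}

#' Read an image stack written by [write_scene()]
#'
#' Reads a multi-page TIFF and its JSON sidecar back into a `scene`.  If
#' the sidecar is missing, pixel size and channel names must be supplied;
#' a warning notes the missing metadata.
#'
#' @param path TIFF path.
#' @param pixel_size override / fallback pixel size, um.
#' @param channels override / fallback channel names, in page order.
#' @return a `scene`, with sidecar annotations (timepoint, cell id)
#'   attached as attributes `timepoint` and `cell_id`.
#' @export
read_stack <- function(path, pixel_size = NULL, channels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  meta <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    warning("no metadata sidecar for ", basename(path),
            "; relying on supplied pixel_size/channels", call. = FALSE)
    if (is.null(pixel_size) || is.null(channels))
      stop("missing metadata: pixel_size and channels must be supplied",
           call. = FALSE)
  }
  px <- if (!is.null(pixel_size)) pixel_size else meta$pixel_size_um
  ch_names <- if (!is.null(channels)) channels else meta$channels
  if (length(ch_names) != length(pages))
    stop("channel names (", length(ch_names), ") do not match pages (",
         length(pages), ")", call. = FALSE)
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  chans <- stats::setNames(lapply(pages, function(m) m * scale), ch_names)
  scene <- structure(list(
    channels = chans,
    pixel_size = px,
    cell_center_um = if (!is.null(meta$cell_center_um))
      meta$cell_center_um else (dim(chans[[1]]) - 1) / 2 * px,
    cell_radius_um = if (!is.null(meta$cell_radius_um))
      meta$cell_radius_um else max(dim(chans[[1]])) * px,
    stage_label = if (!is.null(meta$stage_label)) meta$stage_label
                  else "metaphase"
  ), class = "scene")
  attr(scene, "timepoint") <- if (!is.null(meta$timepoint))
    meta$timepoint else NA_real_
  attr(scene, "cell_id") <- if (!is.null(meta$cell_id)) meta$cell_id
                            else NA_character_
  scene
}

#' Run configuration for the end-to-end pipeline
#'
#' @param image_dir directory of TIFFs written by [write_scene()].
#' @param out_dir output directory.
#' @param channel_map named channel roles; must name `marker` and at least
#'   one signal channel.
#' @param radius_um disk-ROI radius.
#' @param half_length_um line-profile half-length.
#' @param alpha significance level for the recovery test.
#' @param seed seed for background-ROI placement.
#' @param analysis_channel channel analysed by the recovery test.
#' @param pixel_size optional pixel-size override, um.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(image_dir, out_dir,
                       channel_map = c(marker = "marker", rna = "rna"),
                       radius_um = 2, half_length_um = 1, alpha = 0.05,
                       seed = 1L, analysis_channel = "rna",
                       pixel_size = NULL) {
  cfg <- list(image_dir = image_dir, out_dir = out_dir,
              channel_map = as.list(channel_map), radius_um = radius_um,
              half_length_um = half_length_um, alpha = alpha,
              seed = as.integer(seed),
              analysis_channel = analysis_channel,
              pixel_size = pixel_size)
  if (!"marker" %in% names(cfg$channel_map) || length(cfg$channel_map) < 2)
    stop("channel_map must name 'marker' and at least one signal channel",
         call. = FALSE)
  for (f in c("radius_um", "half_length_um", "alpha"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop("run_config field '", f, "' must be positive", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' End-to-end pipeline: detect, quantify, test recovery
#'
#' Reads every TIFF in the configured directory, detects the centrosome
#' pair, quantifies disk enrichment and line-profile peak positions for
#' every mapped channel, and — when the images carry timepoints — runs the
#' washout recovery-onset test.  A cell whose centrosomes cannot be
#' detected is logged and skipped; the run fails only if no cell
#' quantifies.  Outputs: `quant.csv` (one row per centrosome x channel,
#' carrying the configuration hash), `recovery.json` when a time-course is
#' present, and `run.log`.
#'
#' @param config a [run_config()] or path to its YAML.
#' @return invisibly, a list with the quantification tibble, the
#'   `recovery_result` (or NULL), and the config hash.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  hash <- rlang::hash(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("centrofish %s | R %s", as.character(utils::packageVersion("centrofish")),
       paste(R.version$major, R.version$minor, sep = "."))
  logf("config hash %s", hash)
  for (f in setdiff(names(config), "channel_map"))
    logf("  %s = %s", f, paste(format(config[[f]]), collapse = ", "))
  logf("  channel_map = %s",
       paste(names(config$channel_map), unlist(config$channel_map),
             sep = ":", collapse = ", "))

  files <- sort(list.files(config$image_dir, pattern = "\\.tiff?$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no TIFF images in ", config$image_dir,
                               call. = FALSE)
  quant <- purrr::map_dfr(seq_along(files), function(i) {
    f <- files[i]
    tryCatch({
      scene <- read_stack(f, pixel_size = config$pixel_size)
      want <- unlist(config$channel_map)
      missing <- setdiff(want, names(scene$channels))
      if (length(missing) > 0)
        stop("channels not in image: ", paste(missing, collapse = ", "))
      scene$channels <- stats::setNames(
        scene$channels[want], names(config$channel_map))
      cid <- attr(scene, "cell_id")
      if (is.na(cid)) cid <- sub("\\.tiff?$", "", basename(f))
      quantify_scene(scene, cell_id = cid,
                     timepoint = attr(scene, "timepoint"),
                     radius_um = config$radius_um,
                     half_length_um = config$half_length_um,
                     channels = setdiff(names(config$channel_map),
                                        "marker"),
                     seed = config$seed + 977L * i)
    }, error = function(e) {
      logf("SKIP %s: %s", basename(f), conditionMessage(e))
      NULL
    })
  })
  if (nrow(quant) == 0)
    stop("no centrosomes quantified in any image", call. = FALSE)
  quant$config_hash <- hash
  utils::write.csv(quant, file.path(config$out_dir, "quant.csv"),
                   row.names = FALSE)
  logf("quantified %d centrosome-channel records from %d images",
       nrow(quant), length(files))

  recovery <- NULL
  tps <- unique(quant$timepoint)
  if (length(tps[!is.na(tps)]) >= 2 && 0 %in% tps) {
    recovery <- recovery_onset(quant, channel = config$analysis_channel,
                               alpha = config$alpha)
    out <- c(list(config_hash = hash,
                  onset = if (is.na(recovery$onset)) NULL
                          else recovery$onset,
                  alpha = recovery$alpha,
                  channel = recovery$channel),
             list(timepoints = recovery$table))
    jsonlite::write_json(out, file.path(config$out_dir, "recovery.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
    logf("recovery onset: %s h",
         if (is.na(recovery$onset)) "none" else format(recovery$onset))
  }
  invisible(list(quant = quant, recovery = recovery, config_hash = hash))
}
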