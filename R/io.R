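#' Write and read track tables as CSV
#'
#' Tracks travel as comma-separated UTF-8 text with a header row and units
#' suffixed in the column names (`x_um`, `t_s`), the interchange format used
#' by every stage of the pipeline.
#'
#' @param tracks Track tibble (`track_id`, `frame`, `t_s`, `x_um`, `y_um`,
#'   `intensity`).
#' @param path File path.
#' @return `write_tracks_csv()` returns `path` invisibly;
#'   `read_tracks_csv()` returns the track tibble.
#' @export
write_tracks_csv <- function(tracks, path) {
  write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  tibble::as_tibble(read.csv(path))
}

#' Write a movie as multi-page TIFF with a JSON metadata sidecar
#'
#' Frames are stored as 16-bit TIFF pages (counts divided by the
#' `counts_scale` recorded in the sidecar, camera-style); acquisition
#' metadata (pixel size, exposure, frame interval, seed) goes to
#' `<path>.json` so a movie re-read from disk carries its calibration.
#'
#' @param movie A `movie`.
#' @param path Output `.tif` path.
#' @param counts_scale Full-scale count value mapped to the 16-bit maximum.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, counts_scale = 65535) {
  stopifnot(inherits(movie, "movie"))
  scaled <- lapply(movie$frames, function(f) pmin(pmax(f / counts_scale, 0), 1))
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  meta <- list(pixel_size_um = movie$optics$pixel_size,
               exposure_s = movie$optics$exposure,
               frame_interval_s = movie$optics$frame_interval,
               evanescent_depth_nm = movie$optics$evanescent_depth,
               counts_scale = counts_scale,
               seed = movie$metadata$seed %||% NA)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param optics Optics model to attach when the sidecar is missing.
#' @export
read_movie_tiff <- function(path, optics = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(frames)) frames <- list(frames)
  side <- paste0(path, ".json")
  scale <- 1
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    scale <- meta$counts_scale %||% 1
    optics <- optics_model(pixel_size = meta$pixel_size_um,
                           exposure = meta$exposure_s,
                           frame_interval = meta$frame_interval_s,
                           evanescent_depth = meta$evanescent_depth_nm %||% 100)
  } else if (is.null(optics)) {
    abort(sprintf("no sidecar %s; supply `optics`", side))
  }
  frames <- lapply(frames, function(f) f * scale)
  structure(list(frames = frames, optics = optics,
                 metadata = list(path = path)), class = "movie")
}

#' Write ground-truth trajectories as CSV
#'
#' @param truth A `ground_truth`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  write.csv(truth$tracks, path, row.names = FALSE)
  invisible(path)
}
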