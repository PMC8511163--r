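#' Detect and track LAT condensates in a movie
#'
#' Per-frame condensate regions are found by band-pass (difference of
#' Gaussians) filtering, thresholding, and a minimum-area cut; region
#' centroids are linked frame-to-frame with the same linear-assignment
#' linker used for single particles, and only tracks persisting for at
#' least `min_lifetime` frames are counted as condensates. The default
#' persistence threshold of 4 frames at a 2 s lapse suppresses transient
#' intensity fluctuations.
#'
#' @param lat_movie A `movie` (raw frames or pixel-probability maps).
#' @param min_lifetime Minimum track lifetime in frames.
#' @param expected_diameter Condensate diameter, micrometres.
#' @param threshold Band-pass threshold; `NULL` for adaptive.
#' @param min_area_px Minimum region area, pixels.
#' @param max_link_dist Linker radius, micrometres.
#' @return Tibble of condensate tracks: `track_id`, `t_start_s`,
#'   `lifetime_frames`, `x_um`, `y_um` (start centroid), `peak_intensity`.
#' @export
detect_and_track_condensates <- function(lat_movie, min_lifetime = 4,
                                         expected_diameter = 0.6,
                                         threshold = NULL, min_area_px = 4,
                                         max_link_dist = 1) {
  stopifnot(inherits(lat_movie, "movie"))
  px <- lat_movie$optics$pixel_size
  locs <- purrr::imap_dfr(lat_movie$frames, function(fr, i) {
    s1 <- (expected_diameter / 2) / sqrt(2) / px
    dog <- EBImage::gblur(fr, sigma = s1) - EBImage::gblur(fr, sigma = 1.6 * s1)
    thr <- threshold %||% (5 * max(mad(dog), .Machine$double.eps))
    lab <- EBImage::bwlabel(dog > thr)
    nlab <- max(lab)
    if (nlab == 0) return(NULL)
    rows <- purrr::map_dfr(seq_len(nlab), function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      if (nrow(idx) < min_area_px) return(NULL)
      w <- fr[idx]
      tibble::tibble(
        x_um = (sum((idx[, 2] - 0.5) * w) / sum(w)) * px,
        y_um = (sum((idx[, 1] - 0.5) * w) / sum(w)) * px,
        intensity = sum(w), peak = max(w))
    })
    if (is.null(rows) || nrow(rows) == 0) return(NULL)
    dplyr::mutate(rows, frame = i - 1L,
                  t_s = (i - 1L) * lat_movie$optics$frame_interval,
                  .before = 1)
  })
  if (nrow(locs) == 0) {
    return(tibble::tibble(track_id = integer(), t_start_s = double(),
                          lifetime_frames = integer(), x_um = double(),
                          y_um = double(), peak_intensity = double()))
  }
  tracks <- link_tracks(locs, max_link_dist = max_link_dist, max_gap = 1)
  peaks <- locs |>
    dplyr::select("frame", "x_um", "y_um", "peak")
  tracks |>
    dplyr::left_join(peaks, by = c("frame", "x_um", "y_um")) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(t_start_s = min(.data$t_s),
                     lifetime_frames = dplyr::n(),
                     x_um = .data$x_um[which.min(.data$frame)],
                     y_um = .data$y_um[which.min(.data$frame)],
                     peak_intensity = max(.data$peak, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::filter(.data$lifetime_frames >= min_lifetime)
}

#' Per-cell condensate-to-binding-event ratios
#'
#' Counts, for each cell and within the observation window after landing,
#' the number of binding events and the number of persistent condensates,
#' and forms their ratio — the per-binding-event triggering efficiency
#' readout. Background condensates can push the ratio above one. Cells with
#' zero binding events get an undefined ratio and a flag but are kept.
#'
#' @param events Tibble `cell_id`, `t_s` (one row per binding event).
#' @param condensates Tibble `cell_id`, `t_start_s`, `lifetime_frames`.
#' @param window Observation window, seconds (counts restricted to
#'   `[0, window]`).
#' @param min_lifetime Persistence filter applied to `condensates`.
#' @return An `event_ratios` tibble: `cell_id`, `n_binding_events`,
#'   `n_condensates`, `ratio`, `flag`; summary median/IQR in attributes.
#' @examples
#' st <- simulate_event_streams(10, 8, p_condensate = 0.6, rng_seed = 1)
#' compute_event_ratios(st$events, st$condensates)
#' @export
compute_event_ratios <- function(events, condensates, window = 120,
                                 min_lifetime = 4) {
  cell_ids <- sort(union(unique(events$cell_id), unique(condensates$cell_id)))
  ev <- events |> dplyr::filter(.data$t_s >= 0, .data$t_s <= window)
  cd <- condensates |>
    dplyr::filter(.data$lifetime_frames >= min_lifetime,
                  .data$t_start_s >= 0, .data$t_start_s <= window)
  out <- purrr::map_dfr(cell_ids, function(ci) {
    nb <- sum(ev$cell_id == ci)
    nc <- sum(cd$cell_id == ci)
    tibble::tibble(cell_id = ci, n_binding_events = nb, n_condensates = nc,
                   ratio = if (nb > 0) nc / nb else NA_real_,
                   flag = if (nb > 0) "ok" else "no_binding_events")
  })
  r <- out$ratio[!is.na(out$ratio)]
  structure(out, class = c("event_ratios", class(out)),
            summary = list(median = median(r), iqr = quantile(r, c(.25, .75)),
                           n_cells = length(cell_ids)))
}

#' Compare per-cell event ratios between two ligand groups
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test with tie correction,
#' with the significance-star convention `****` p < 0.0001, `***` p < 0.001,
#' `**` p < 0.01, and `ns` above 0.01.
#'
#' @param ratios_a,ratios_b Numeric vectors of per-cell ratios, or
#'   `event_ratios` tibbles (their `ratio` columns are used; undefined
#'   ratios dropped).
#' @return One-row tibble: `u_statistic`, `p_value`, `significance`,
#'   `n_a`, `n_b`.
#' @export
compare_groups <- function(ratios_a, ratios_b) {
  get_r <- function(x) {
    if (is.data.frame(x)) x <- x$ratio
    x[!is.na(x)]
  }
  a <- get_r(ratios_a); b <- get_r(ratios_b)
  if (length(a) < 5 || length(b) < 5) {
    warn("fewer than 5 ratios in a group; rank test will have little power")
  }
  wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  p <- wt$p.value
  stars <- if (p < 1e-4) "****" else if (p < 1e-3) "***" else
    if (p < 0.01) "**" else "ns"
  tibble::tibble(u_statistic = unname(wt$statistic), p_value = p,
                 significance = stars, n_a = length(a), n_b = length(b))
}

#' Label binding events by condensate colocalization
#'
#' A binding event is colocalized when some condensate initiates within
#' `radius` of the event and within `[0, max_lag]` seconds after the event
#' start — the "condensate a handful of seconds later, right on top of the
#' event" signature of successful receptor triggering.
#'
#' @param events Tibble `t_s`, `x_um`, `y_um` (optionally `cell_id`; events
#'   and condensates are then matched within cells).
#' @param condensates Tibble `t_start_s`, `x_um`, `y_um` (and `cell_id` if
#'   used in `events`).
#' @param radius Colocalization radius, micrometres.
#' @param max_lag Maximum nucleation delay, seconds.
#' @return `events` with a logical `colocalized` column.
#' @export
colocalize_events <- function(events, condensates, radius = 0.5,
                              max_lag = 10) {
  .assert_scalar_pos(radius, "radius")
  .assert_scalar_pos(max_lag, "max_lag")
  by_cell <- "cell_id" %in% names(events) && "cell_id" %in% names(condensates)
  lab <- vapply(seq_len(nrow(events)), function(i) {
    cd <- condensates
    if (by_cell) cd <- cd[cd$cell_id == events$cell_id[i], , drop = FALSE]
    if (nrow(cd) == 0) return(FALSE)
    dt <- cd$t_start_s - events$t_s[i]
    d2 <- (cd$x_um - events$x_um[i])^2 + (cd$y_um - events$y_um[i])^2
    any(dt >= 0 & dt <= max_lag & d2 <= radius^2)
  }, logical(1))
  dplyr::mutate(events, colocalized = lab)
}

#' Render a synthetic LAT condensate movie
#'
#' Paints Gaussian condensate blobs onto noisy background frames at given
#' positions, start times and lifetimes — the ground-truth input for testing
#' condensate detection and the persistence filter.
#'
#' @param condensates Tibble `t_start_s`, `x_um`, `y_um`, `lifetime_frames`.
#' @param optics An [optics_model()] (frame interval sets the 2 s lapse).
#' @param n_frames,box_size Movie dimensions.
#' @param amplitude Peak expected photons per condensate per frame.
#' @param sigma_um Condensate Gaussian radius.
#' @param noise Add camera noise?
#' @return A `movie`.
#' @export
render_condensate_movie <- function(condensates,
                                    optics = optics_model(
                                      pixel_size = 0.1067, psf_sigma = 0.2,
                                      exposure = 0.1, frame_interval = 2,
                                      photon_rate = 2000),
                                    n_frames = 60, box_size = 10,
                                    amplitude = 800, sigma_um = 0.25,
                                    noise = TRUE) {
  npx <- as.integer(ceiling(box_size / optics$pixel_size))
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames) - 1L) {
    t0 <- f * optics$frame_interval
    img <- matrix(0, npx, npx)
    live <- which(condensates$t_start_s <= t0 &
                    t0 < condensates$t_start_s +
                    condensates$lifetime_frames * optics$frame_interval)
    if (length(live)) {
      img <- .stamp_psf(img, condensates$x_um[live], condensates$y_um[live],
                        rep(amplitude, length(live)), sigma_um,
                        optics$pixel_size)$img
    }
    if (noise) {
      img <- matrix(rpois(length(img), img) * optics$gain + optics$baseline +
                      rnorm(length(img), 0, optics$read_noise_sd), npx)
    } else {
      img <- img * optics$gain + optics$baseline
    }
    frames[[f + 1L]] <- img
  }
  structure(list(frames = frames, optics = optics,
                 metadata = list(n_condensates = nrow(condensates))),
            class = "movie")
}
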