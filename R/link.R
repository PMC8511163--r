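#' Link localisations into particle tracks
#'
#' Frame-to-frame linking by global linear-assignment-problem (LAP)
#' optimisation: candidate links cost their squared displacement, capped at
#' `max_link_dist`; every spot may instead start or terminate a track at the
#' cost of the cap, and the assignment minimising total cost is found with a
#' Hungarian-method solver. Tracks whose particle is missed may be bridged
#' across up to `max_gap` skipped frames. A greedy nearest-neighbour linker
#' is provided for cross-checking (`method = "greedy"`); ties there are
#' broken by smallest displacement, then lowest spot index, so both methods
#' are deterministic.
#'
#' @param locs Tibble of localisations with columns `frame` (0-based
#'   integers), `x_um`, `y_um`, and optionally `t_s` and `intensity`.
#' @param max_link_dist Maximum frame-to-frame displacement, micrometres.
#'   A sensible default is `3 * sqrt(4 * D_expected * dt)`.
#' @param max_gap Maximum number of consecutive missed frames bridged.
#' @param method `"lap"` (default) or `"greedy"`.
#' @return Tibble `track_id`, `frame`, `t_s`, `x_um`, `y_um`, `intensity`,
#'   ordered by track then frame.
#' @examples
#' locs <- tibble::tibble(frame = rep(0:4, each = 2),
#'                        x_um = rep(c(1, 6), 5), y_um = rep(c(1, 1), 5))
#' link_tracks(locs, max_link_dist = 1)
#' @export
link_tracks <- function(locs, max_link_dist, max_gap = 0,
                        method = c("lap", "greedy")) {
  method <- match.arg(method)
  .assert_scalar_pos(max_link_dist, "max_link_dist", strict = FALSE)
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(locs)))
  if (nrow(locs) == 0L) {
    return(tibble::tibble(track_id = integer(), frame = integer(),
                          t_s = double(), x_um = double(), y_um = double(),
                          intensity = double()))
  }
  if (!"t_s" %in% names(locs)) locs$t_s <- NA_real_
  if (!"intensity" %in% names(locs)) locs$intensity <- NA_real_
  locs <- dplyr::arrange(locs, .data$frame)
  locs$.row <- seq_len(nrow(locs))
  track_of <- integer(nrow(locs))

  frames <- sort(unique(locs$frame))
  by_frame <- split(locs, locs$frame)

  # active track heads: track id, last frame, last position
  act_id <- integer(0); act_frame <- integer(0)
  act_x <- numeric(0); act_y <- numeric(0)
  next_id <- 1L

  for (f in frames) {
    cur <- by_frame[[as.character(f)]]
    ncur <- nrow(cur)
    live <- which(act_frame >= f - 1L - max_gap)
    assigned <- rep(NA_integer_, ncur)  # index into live
    if (length(live) && ncur && max_link_dist > 0) {
      d2 <- outer(seq_along(live), seq_len(ncur), function(i, j) {
        (act_x[live[i]] - cur$x_um[j])^2 + (act_y[live[i]] - cur$y_um[j])^2
      })
      d2[d2 > max_link_dist^2] <- NA
      assigned <- if (method == "lap") {
        .assign_lap(d2, max_link_dist^2)
      } else {
        .assign_greedy(d2)
      }
    }
    for (j in seq_len(ncur)) {
      if (!is.na(assigned[j])) {
        k <- live[assigned[j]]
        track_of[cur$.row[j]] <- act_id[k]
        act_frame[k] <- f; act_x[k] <- cur$x_um[j]; act_y[k] <- cur$y_um[j]
      } else {
        track_of[cur$.row[j]] <- next_id
        act_id <- c(act_id, next_id); act_frame <- c(act_frame, f)
        act_x <- c(act_x, cur$x_um[j]); act_y <- c(act_y, cur$y_um[j])
        next_id <- next_id + 1L
      }
    }
  }

  locs$track_id <- track_of
  locs |>
    dplyr::select("track_id", "frame", "t_s", "x_um", "y_um", "intensity") |>
    dplyr::arrange(.data$track_id, .data$frame)
}

# global assignment on the Jaqaman-style augmented cost matrix:
# top-left = link costs, diagonal blocks = birth/death at the cap cost
.assign_lap <- function(d2, cap) {
  n1 <- nrow(d2); n2 <- ncol(d2)
  if (all(is.na(d2))) return(rep(NA_integer_, n2))
  big <- cap * (n1 + n2 + 1) + 1
  m <- matrix(big, n1 + n2, n1 + n2)
  link <- d2; link[is.na(link)] <- big
  m[seq_len(n1), seq_len(n2)] <- link
  for (i in seq_len(n1)) m[i, n2 + i] <- cap            # track death
  for (j in seq_len(n2)) m[n1 + j, j] <- cap            # track birth
  m[(n1 + 1):(n1 + n2), (n2 + 1):(n2 + n1)] <- 0        # bookkeeping block
  sol <- clue::solve_LSAP(m)
  assigned <- rep(NA_integer_, n2)
  for (i in seq_len(n1)) {
    j <- sol[i]
    if (j <= n2 && !is.na(d2[i, j])) assigned[j] <- i
  }
  assigned
}

# greedy: repeatedly take the smallest remaining displacement; ties broken
# by lowest (row, col) index via matrix order
.assign_greedy <- function(d2) {
  n2 <- ncol(d2)
  assigned <- rep(NA_integer_, n2)
  d <- d2
  repeat {
    if (all(is.na(d))) break
    k <- which(d == min(d, na.rm = TRUE))[1]
    i <- (k - 1) %% nrow(d) + 1
    j <- (k - 1) %/% nrow(d) + 1
    assigned[j] <- i
    d[i, ] <- NA; d[, j] <- NA
  }
  assigned
}

#' Track a movie end-to-end
#'
#' Convenience wrapper: [detect_movie()] then [link_tracks()].
#'
#' @param movie A `movie`.
#' @param expected_diameter,threshold Passed to the detector.
#' @param max_link_dist,max_gap,method Passed to the linker; the default
#'   link radius is `3 * sqrt(4 * d_expected * frame_interval)`.
#' @param d_expected Diffusivity used for the default link radius, um^2/s.
#' @return Track tibble as from [link_tracks()].
#' @export
track_movie <- function(movie, expected_diameter = 0.4, threshold = NULL,
                        d_expected = 2.5, max_link_dist = NULL,
                        max_gap = 0, method = "lap") {
  if (is.null(max_link_dist)) {
    max_link_dist <- 3 * sqrt(4 * d_expected * movie$optics$frame_interval)
  }
  locs <- detect_movie(movie, expected_diameter, threshold)
  link_tracks(locs, max_link_dist, max_gap, method)
}
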