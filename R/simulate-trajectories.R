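#' Simulate ligand trajectories on a supported lipid bilayer
#'
#' Forward-simulates 2-D Brownian motion of membrane-tethered ligands with
#' stochastic switching between a fast free state and a slow receptor-bound
#' state, single-step photobleaching, and a per-molecule fluorophore height.
#' This is the ground-truth generator for every downstream stage: rendered
#' movies, step-size distributions, dwell-time records and fraction-bound
#' frames all derive from its output.
#'
#' Motion is advanced on a sub-frame grid (`sub_steps` positions per
#' exposure, so rendered images carry realistic motion blur) plus one jump
#' over the dark gap between exposures. Free-state displacements per axis
#' over an interval `dt` are Gaussian with variance `2 * d_free * dt`
#' (bound state likewise with `d_bound`); boundaries reflect. Bound-state
#' dwell times are exponential with mean `tau_off_true`. Bleach times are
#' exponential with mean `tau_bleach_true` on a clock that only advances
#' while the field is illuminated; bleaching is absorbing.
#'
#' @param cfg A [sim_config()].
#' @param optics An [optics_model()] supplying exposure and frame timing.
#' @param sub_steps Sub-steps per exposure (>= 10 required for rendering).
#' @param n_molecules Override the Poisson(`density * box_size^2`) molecule
#'   count with a fixed number.
#' @param p_bound0 Probability that a molecule starts in the bound state.
#'
#' @return An object of class `ground_truth`: a list with
#'   * `tracks`: tibble of frame-start positions (`molecule_id`, `frame`
#'     (0-based), `t_s`, `x_um`, `y_um`, `height_nm`, `state`),
#'   * `fine`: tibble of all sub-exposure positions (only when
#'     `sub_steps > 1`), with an `illuminated` flag,
#'   * `dwells`: tibble of true bound intervals (`molecule_id`, `start_s`,
#'     `duration_s`, `censored`),
#'   * `config`, `optics`, `n_molecules`, `seed`.
#' @examples
#' gt <- simulate_trajectories(sim_config(n_frames = 20, rng_seed = 7),
#'                             optics_model(exposure = 0.02, frame_interval = 0.02),
#'                             sub_steps = 1)
#' head(gt$tracks)
#' @export
simulate_trajectories <- function(cfg,
                                  optics = optics_model(exposure = 0.02,
                                                        frame_interval = 0.02),
                                  sub_steps = 10,
                                  n_molecules = NULL,
                                  p_bound0 = if (cfg$k_on_app > 0) NA else 0) {
  stopifnot(inherits(cfg, "sim_config"), inherits(optics, "optics_model"))
  .assert_scalar_pos(sub_steps, "sub_steps")
  set.seed(cfg$rng_seed)

  n <- if (is.null(n_molecules)) rpois(1L, cfg$density * cfg$box_size^2) else
    as.integer(n_molecules)
  if (n == 0L) {
    return(structure(list(tracks = .empty_track_tbl(), fine = NULL,
                          dwells = .empty_dwell_tbl(), config = cfg,
                          optics = optics, n_molecules = 0L,
                          seed = cfg$rng_seed, sub_steps = sub_steps),
                     class = "ground_truth"))
  }

  # stationary bound probability when switching is on and none requested
  if (is.na(p_bound0)) {
    k_off <- if (is.finite(cfg$tau_off_true)) 1 / cfg$tau_off_true else 0
    p_bound0 <- if (cfg$k_on_app + k_off > 0) cfg$k_on_app / (cfg$k_on_app + k_off) else 0
  }

  x <- runif(n, 0, cfg$box_size)
  y <- runif(n, 0, cfg$box_size)
  h <- .draw_heights(n, cfg)
  bound <- runif(n) < p_bound0
  bleach_budget <- if (is.finite(cfg$tau_bleach_true))
    rexp(n, 1 / cfg$tau_bleach_true) else rep(Inf, n)
  illum_time <- numeric(n)
  bleached <- rep(FALSE, n)

  exp_dt <- optics$exposure / sub_steps
  gap <- optics$frame_interval - optics$exposure
  k_off <- if (is.finite(cfg$tau_off_true)) 1 / cfg$tau_off_true else 0
  k_on <- cfg$k_on_app

  nf <- cfg$n_frames
  keep_fine <- sub_steps > 1
  # preallocate
  frame_rows <- vector("list", nf)
  fine_rows <- if (keep_fine) vector("list", nf) else NULL
  bind_start <- ifelse(bound, 0, NA_real_)
  dwell_acc <- list()

  t_now <- 0
  for (f in seq_len(nf) - 1L) {
    frame_rows[[f + 1L]] <- tibble::tibble(
      molecule_id = seq_len(n), frame = f, t_s = t_now,
      x_um = x, y_um = y, height_nm = h,
      state = ifelse(bleached, "bleached", ifelse(bound, "bound", "free")))
    if (keep_fine) {
      sx <- matrix(NA_real_, n, sub_steps); sy <- sx
      sb <- matrix(FALSE, n, sub_steps)
    }
    for (s in seq_len(sub_steps)) {
      if (keep_fine) { sx[, s] <- x; sy[, s] <- y; sb[, s] <- bleached }
      # illumination advances the bleach clock for this sub-step
      newly <- !bleached & (illum_time + exp_dt >= bleach_budget)
      illum_time <- illum_time + exp_dt
      bleached <- bleached | newly
      upd <- .advance(x, y, bound, bind_start, t_now, exp_dt, cfg, k_on, k_off)
      x <- upd$x; y <- upd$y; bound <- upd$bound
      bind_start <- upd$bind_start; dwell_acc <- c(dwell_acc, upd$dwells)
      t_now <- t_now + exp_dt
    }
    if (keep_fine) {
      fine_rows[[f + 1L]] <- tibble::tibble(
        molecule_id = rep(seq_len(n), sub_steps),
        frame = f,
        sub = rep(seq_len(sub_steps), each = n),
        t_s = rep(t_now - optics$exposure + (seq_len(sub_steps) - 1L) * exp_dt,
                  each = n),
        x_um = as.vector(sx), y_um = as.vector(sy),
        height_nm = rep(h, sub_steps),
        bleached = as.vector(sb), illuminated = TRUE)
    }
    if (gap > 0) {
      upd <- .advance(x, y, bound, bind_start, t_now, gap, cfg, k_on, k_off)
      x <- upd$x; y <- upd$y; bound <- upd$bound
      bind_start <- upd$bind_start; dwell_acc <- c(dwell_acc, upd$dwells)
      t_now <- t_now + gap
    }
  }
  # close out open bound intervals as censored
  open <- which(!is.na(bind_start))
  if (length(open)) {
    dwell_acc <- c(dwell_acc, list(tibble::tibble(
      molecule_id = open, start_s = bind_start[open],
      duration_s = t_now - bind_start[open], censored = TRUE)))
  }
  dwells <- if (length(dwell_acc)) dplyr::bind_rows(dwell_acc) else .empty_dwell_tbl()
  dwells <- dplyr::arrange(dwells, .data$molecule_id, .data$start_s)

  structure(list(
    tracks = dplyr::bind_rows(frame_rows),
    fine = if (keep_fine) dplyr::bind_rows(fine_rows) else NULL,
    dwells = dwells, config = cfg, optics = optics,
    n_molecules = n, seed = cfg$rng_seed, sub_steps = sub_steps),
    class = "ground_truth")
}

# one diffusion + state-switching step over dt (vectorised over molecules)
.advance <- function(x, y, bound, bind_start, t_now, dt, cfg, k_on, k_off) {
  n <- length(x)
  sd_step <- sqrt(2 * ifelse(bound, cfg$d_bound, cfg$d_free) * dt)
  x <- .reflect(x + rnorm(n, 0, sd_step), cfg$box_size)
  y <- .reflect(y + rnorm(n, 0, sd_step), cfg$box_size)
  dwells <- list()
  if (k_off > 0) {
    unbind <- bound & runif(n) < (1 - exp(-k_off * dt))
    if (any(unbind)) {
      idx <- which(unbind)
      dwells <- list(tibble::tibble(
        molecule_id = idx, start_s = bind_start[idx],
        duration_s = t_now + dt - bind_start[idx], censored = FALSE))
      bound[idx] <- FALSE
      bind_start[idx] <- NA_real_
    }
  }
  if (k_on > 0) {
    bind <- !bound & runif(n) < (1 - exp(-k_on * dt))
    if (any(bind)) {
      bound[bind] <- TRUE
      bind_start[bind] <- t_now + dt
    }
  }
  list(x = x, y = y, bound = bound, bind_start = bind_start, dwells = dwells)
}

.reflect <- function(u, box) {
  # fold positions back into [0, box] (handles multiple reflections)
  u <- u %% (2 * box)
  ifelse(u > box, 2 * box - u, u)
}

.draw_heights <- function(n, cfg) {
  if (cfg$fluorophore_height_max <= 0) return(rep(cfg$height_mean, n))
  if (cfg$height_sd <= 0) return(rep(min(cfg$height_mean, cfg$fluorophore_height_max), n))
  # truncated Gaussian on [0, contour length] by rejection
  h <- numeric(0)
  while (length(h) < n) {
    cand <- rnorm(2L * n, cfg$height_mean, cfg$height_sd)
    h <- c(h, cand[cand >= 0 & cand <= cfg$fluorophore_height_max])
  }
  h[seq_len(n)]
}

.empty_track_tbl <- function() {
  tibble::tibble(molecule_id = integer(), frame = integer(), t_s = double(),
                 x_um = double(), y_um = double(), height_nm = double(),
                 state = character())
}
.empty_dwell_tbl <- function() {
  tibble::tibble(molecule_id = integer(), start_s = double(),
                 duration_s = double(), censored = logical())
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  cat(sprintf("  %d molecules, %d frames, seed %d\n",
              x$n_molecules, x$config$n_frames, x$seed))
  cat(sprintf("  %d recorded bound intervals\n", nrow(x$dwells)))
  invisible(x)
}

#' Frame-level tracks from a ground-truth simulation
#'
#' Extracts the unbleached frame-start localisations in the CSV track layout
#' used across the package, so simulator output can feed the analysis stages
#' directly (bypassing detection) when testing estimators in isolation.
#'
#' @param truth A `ground_truth` object.
#' @param states Character vector of states to keep.
#' @return Tibble with `track_id`, `frame`, `t_s`, `x_um`, `y_um`, `intensity`.
#' @export
truth_tracks <- function(truth, states = c("free", "bound")) {
  stopifnot(inherits(truth, "ground_truth"))
  truth$tracks |>
    dplyr::filter(.data$state %in% states) |>
    dplyr::transmute(track_id = .data$molecule_id, frame = .data$frame,
                     t_s = .data$t_s, x_um = .data$x_um, y_um = .data$y_um,
                     intensity = NA_real_)
}
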