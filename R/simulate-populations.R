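#' Simulate single-particle photobleaching intensity traces
#'
#' Generates camera intensity traces for particles carrying one or more
#' fluorophores, each of which bleaches in a single step at an independent
#' exponential time. Noise combines Poisson shot noise on the emitted signal
#' with Gaussian read noise, scaled so the single-fluorophore step height
#' divided by the background noise SD equals `snr`.
#'
#' @param n_traces Number of traces.
#' @param n_fluor Fluorophores per particle (1 for a monovalent ligand;
#'   recycled across traces).
#' @param tau_bleach_frames Mean bleach time, frames.
#' @param n_frames Trace length, frames; traces always extend to background
#'   (bleach times are resampled to fall inside the trace).
#' @param snr Single-fluorophore step height over background noise SD.
#' @param frame_interval Seconds per frame (for the `t_s` column).
#' @param unit_intensity Counts per fluorophore.
#' @param rng_seed Seed.
#' @return Tibble `trace_id`, `t_s`, `intensity`, plus a `true_steps` column
#'   (the number of fluorophores) constant within each trace.
#' @examples
#' tr <- simulate_bleach_traces(3, n_fluor = 1, rng_seed = 9)
#' dplyr::count(tr, trace_id)
#' @export
simulate_bleach_traces <- function(n_traces, n_fluor = 1,
                                   tau_bleach_frames = 30,
                                   n_frames = 120, snr = 5,
                                   frame_interval = 0.02,
                                   unit_intensity = 1000,
                                   rng_seed = 1L) {
  .assert_scalar_pos(n_traces, "n_traces")
  .assert_scalar_pos(snr, "snr")
  set.seed(as.integer(rng_seed))
  n_fluor <- rep_len(as.integer(n_fluor), n_traces)
  noise_sd <- unit_intensity / snr
  out <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    k <- n_fluor[i]
    # resample bleach frames so every emission level lasts >= 3 frames:
    # each plateau must be resolvable by the change-point counter (a
    # particle bleaching within 1-2 frames never enters a trace in a real
    # pipeline), and the trace must reach background at the end
    repeat {
      bleach_at <- sort(ceiling(rexp(k, 1 / tau_bleach_frames)))
      if (all(bleach_at >= 3 & bleach_at < n_frames - 3) &&
          (k < 2 || all(diff(bleach_at) >= 3))) break
    }
    level <- vapply(seq_len(n_frames),
                    function(f) sum(bleach_at >= f) * unit_intensity, 0)
    intensity <- level + rnorm(n_frames, 0, noise_sd)
    out[[i]] <- tibble::tibble(trace_id = i,
                               t_s = (seq_len(n_frames) - 1L) * frame_interval,
                               intensity = intensity, true_steps = k)
  }
  dplyr::bind_rows(out)
}

#' Simulate observed binding-event dwell records
#'
#' Draws binding events whose true dwell times are exponential with mean
#' `tau_off`, observed by time-lapse imaging. An event's visible lifetime
#' ends at the earliest of unbinding, photobleaching (exponential with mean
#' `tau_bleach` on the acquisition clock — bleaching is indistinguishable
#' from unbinding in the image, which is why the downstream fit must correct
#' for it), and track loss at `censor_time` (movie end or arrival at the
#' dense cell-centre region where tracking fails). Durations are reported as
#' whole frames of the `lapse` interval; events ended by track loss are
#' right-censored.
#'
#' @param n_events Number of binding events.
#' @param tau_off True mean dwell time, seconds.
#' @param tau_bleach Mean bleach time on the acquisition clock, seconds
#'   (`Inf` disables bleaching).
#' @param lapse Time lapse between frames, seconds.
#' @param censor_time Track-loss time after binding, seconds (`Inf` for
#'   none). May be a vector of per-event loss times.
#' @param rng_seed Seed.
#' @return Tibble of dwell records: `duration_s` (positive multiple of
#'   `lapse`), `censored`, `start_frame`.
#' @examples
#' simulate_dwell_records(5, tau_off = 50, rng_seed = 3)
#' @export
simulate_dwell_records <- function(n_events, tau_off, tau_bleach = Inf,
                                   lapse = 10, censor_time = Inf,
                                   rng_seed = 1L) {
  .assert_scalar_pos(n_events, "n_events")
  .assert_scalar_pos(tau_off, "tau_off", finite = FALSE)
  .assert_scalar_pos(tau_bleach, "tau_bleach", finite = FALSE)
  .assert_scalar_pos(lapse, "lapse")
  set.seed(as.integer(rng_seed))
  t_off <- rexp(n_events, 1 / tau_off)
  t_bl <- if (is.finite(tau_bleach)) rexp(n_events, 1 / tau_bleach) else
    rep(Inf, n_events)
  t_cens <- rep_len(censor_time, n_events)
  visible_end <- pmin(t_off, t_bl)
  censored <- t_cens < visible_end
  obs <- pmin(visible_end, t_cens)
  # an event present for any part of a frame is seen for that whole frame
  duration <- pmax(ceiling(obs / lapse), 1) * lapse
  tibble::tibble(duration_s = duration, censored = censored,
                 start_frame = 0L)
}

#' Simulate a T cell activation population for dose-response fitting
#'
#' Each simulated cell activates (NFAT translocates to the nucleus) with a
#' Hill-type probability of the ligand surface density it experiences:
#' `p(rho) = max_resp * rho^hill / (rho^hill + ec50^hill)`.
#'
#' @param densities Ligand densities, molecules per square micrometre.
#' @param ec50 Half-maximal density, same units.
#' @param hill Hill coefficient (> 0).
#' @param max_resp Maximal activated fraction, in (0, 1].
#' @param n_cells Cells per density (recycled across densities).
#' @param rng_seed Seed.
#' @return Tibble `density`, `cell_id`, `activated` (logical).
#' @examples
#' pop <- simulate_activation_population(c(0.1, 0.3, 1), ec50 = 0.3,
#'                                       hill = 2, max_resp = 0.9,
#'                                       n_cells = 50, rng_seed = 4)
#' dplyr::summarise(dplyr::group_by(pop, density), frac = mean(activated))
#' @export
simulate_activation_population <- function(densities, ec50, hill = 2,
                                           max_resp = 0.9, n_cells = 200,
                                           rng_seed = 1L) {
  if (any(!is.finite(densities)) || any(densities <= 0)) {
    abort("`densities` must be positive and finite")
  }
  .assert_scalar_pos(ec50, "ec50")
  .assert_scalar_pos(hill, "hill")
  if (max_resp <= 0 || max_resp > 1) abort("`max_resp` must be in (0, 1]")
  set.seed(as.integer(rng_seed))
  n_cells <- rep_len(as.integer(n_cells), length(densities))
  purrr::map2_dfr(densities, n_cells, function(rho, nc) {
    p <- max_resp * rho^hill / (rho^hill + ec50^hill)
    tibble::tibble(density = rho, cell_id = seq_len(nc),
                   activated = runif(nc) < p)
  })
}

#' Simulate per-cell binding-event and LAT-condensate streams
#'
#' Generates the paired event streams scored by the condensate-per-binding-
#' event analysis. Binding events per cell are Poisson; each event
#' independently nucleates a persistent condensate (lifetime >= 4 frames)
#' with probability `p_condensate`, a handful of seconds after and close to
#' the binding event. Background condensates unrelated to binding are added
#' at `background_rate` per cell.
#'
#' @param n_cells Number of cells.
#' @param events_per_cell_mean Mean binding events per cell in the window.
#' @param p_condensate Per-event condensation probability, in \[0, 1\].
#' @param background_rate Mean background condensates per cell.
#' @param window_s Observation window after cell landing, seconds.
#' @param frame_interval Seconds between condensate-channel frames.
#' @param lag_mean_s Mean delay from binding to condensate nucleation, s.
#' @param jitter_um SD of the condensate offset from its binding event, um.
#' @param rng_seed Seed.
#' @return List of two tibbles: `events` (`cell_id`, `event_id`, `t_s`,
#'   `x_um`, `y_um`) and `condensates` (`cell_id`, `cond_id`, `t_start_s`,
#'   `x_um`, `y_um`, `lifetime_frames`, `from_event`).
#' @examples
#' st <- simulate_event_streams(3, 5, p_condensate = 0.6, rng_seed = 5)
#' st$events; st$condensates
#' @export
simulate_event_streams <- function(n_cells, events_per_cell_mean,
                                   p_condensate, background_rate = 0,
                                   window_s = 120, frame_interval = 2,
                                   lag_mean_s = 5, jitter_um = 0.2,
                                   rng_seed = 1L) {
  .assert_scalar_pos(n_cells, "n_cells")
  .assert_scalar_pos(events_per_cell_mean, "events_per_cell_mean", strict = FALSE)
  if (p_condensate < 0 || p_condensate > 1) abort("`p_condensate` must be in [0, 1]")
  .assert_scalar_pos(background_rate, "background_rate", strict = FALSE)
  set.seed(as.integer(rng_seed))
  ev <- list(); cd <- list()
  footprint_r <- 5  # um, cells land near the field centre
  for (ci in seq_len(n_cells)) {
    ne <- rpois(1, events_per_cell_mean)
    if (ne > 0) {
      th <- runif(ne, 0, 2 * pi); rr <- footprint_r * sqrt(runif(ne))
      e <- tibble::tibble(cell_id = ci, event_id = seq_len(ne),
                          t_s = sort(runif(ne, 0, window_s)),
                          x_um = footprint_r + rr * cos(th),
                          y_um = footprint_r + rr * sin(th))
      ev[[length(ev) + 1L]] <- e
      trig <- runif(ne) < p_condensate
      if (any(trig)) {
        idx <- which(trig)
        cd[[length(cd) + 1L]] <- tibble::tibble(
          cell_id = ci, cond_id = NA_integer_,
          t_start_s = e$t_s[idx] + rexp(length(idx), 1 / lag_mean_s),
          x_um = e$x_um[idx] + rnorm(length(idx), 0, jitter_um),
          y_um = e$y_um[idx] + rnorm(length(idx), 0, jitter_um),
          lifetime_frames = 4L + rpois(length(idx), 3),
          from_event = e$event_id[idx])
      }
    }
    nb <- rpois(1, background_rate)
    if (nb > 0) {
      th <- runif(nb, 0, 2 * pi); rr <- footprint_r * sqrt(runif(nb))
      cd[[length(cd) + 1L]] <- tibble::tibble(
        cell_id = ci, cond_id = NA_integer_,
        t_start_s = runif(nb, 0, window_s),
        x_um = footprint_r + rr * cos(th),
        y_um = footprint_r + rr * sin(th),
        lifetime_frames = 4L + rpois(nb, 3),
        from_event = NA_integer_)
    }
  }
  events <- if (length(ev)) dplyr::bind_rows(ev) else
    tibble::tibble(cell_id = integer(), event_id = integer(), t_s = double(),
                   x_um = double(), y_um = double())
  condensates <- if (length(cd)) dplyr::bind_rows(cd) else
    tibble::tibble(cell_id = integer(), cond_id = integer(),
                   t_start_s = double(), x_um = double(), y_um = double(),
                   lifetime_frames = integer(), from_event = integer())
  if (nrow(condensates)) {
    condensates <- condensates |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::mutate(cond_id = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  list(events = events, condensates = condensates)
}
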