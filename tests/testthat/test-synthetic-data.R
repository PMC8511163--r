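test_that("config constructors validate their inputs", {
  expect_error(optics_model(exposure = 1, frame_interval = 0.5), "exposure")
  expect_error(optics_model(pixel_size = -1), "pixel_size")
  expect_error(sim_config(d_free = 0.01, d_bound = 2), "d_bound")
  expect_error(sim_config(tau_off_true = -5), "tau_off_true")
  expect_error(sim_config(density = NA), "density")
})

test_that("zero diffusivity keeps every molecule in place", {
  gt <- simulate_trajectories(
    sim_config(box_size = 10, d_free = 0, d_bound = 0, n_frames = 10,
               rng_seed = 1),
    quick_optics(), sub_steps = 1, n_molecules = 5)
  spread <- gt$tracks |>
    dplyr::group_by(molecule_id) |>
    dplyr::summarise(sx = stats::sd(x_um), sy = stats::sd(y_um))
  expect_true(all(spread$sx == 0 & spread$sy == 0))
})

test_that("free-state mean squared displacement matches 4 D dt", {
  d_free <- 2.49; dt <- 0.02
  gt <- simulate_trajectories(
    sim_config(box_size = 300, d_free = d_free, n_frames = 101, rng_seed = 42),
    quick_optics(), sub_steps = 1, n_molecules = 100)  # 10^4 steps
  tr <- truth_tracks(gt)
  steps <- build_step_distributions(tr, dt, dt)
  msd <- mean(steps$r_um^2)
  se <- stats::sd(steps$r_um^2) / sqrt(nrow(steps))
  expect_lt(abs(msd - 4 * d_free * dt), 3 * se)
})

test_that("MSD scales linearly in the delay (4 D tau at every tested tau)", {
  gt <- simulate_trajectories(
    sim_config(box_size = 300, d_free = 2, n_frames = 101, rng_seed = 7),
    quick_optics(), sub_steps = 1, n_molecules = 80)
  steps <- build_step_distributions(truth_tracks(gt), c(0.02, 0.04, 0.06), 0.02)
  for (tau in c(0.02, 0.04, 0.06)) {
    r <- steps$r_um[steps$delay_s == tau]
    se <- stats::sd(r^2) / sqrt(length(r))
    expect_lt(abs(mean(r^2) - 4 * 2 * tau), 3 * se)
  }
})

test_that("ground-truth dwell durations are exponential with the set mean", {
  # window of 40 tau and dwells starting in the first half, so truncation
  # of long dwells is negligible; sub-step discretisation is 1% of tau
  tau <- 5
  gt <- simulate_trajectories(
    sim_config(box_size = 30, density = 0.1, d_free = 2.5, k_on_app = 0.3,
               tau_off_true = tau, n_frames = 4000, rng_seed = 3),
    optics_model(exposure = 0.05, frame_interval = 0.05), sub_steps = 1)
  done <- gt$dwells[!gt$dwells$censored & gt$dwells$start_s < 100, ]
  expect_gt(nrow(done), 100)
  se <- stats::sd(done$duration_s) / sqrt(nrow(done))
  expect_lt(abs(mean(done$duration_s) - tau), 3 * se)
  ks <- suppressWarnings(stats::ks.test(done$duration_s, stats::pexp,
                                        rate = 1 / tau))
  expect_gt(ks$p.value, 0.01)
})

test_that("direct dwell-record generator reproduces the ~50 s benchmark mean", {
  rec <- simulate_dwell_records(1000, tau_off = 50, lapse = 10, rng_seed = 5)
  # interval recording rounds up to the frame: subtract the expected half-frame
  m <- mean(rec$duration_s) - 10 / 2
  se <- stats::sd(rec$duration_s) / sqrt(nrow(rec))
  expect_lt(abs(m - 50), 3 * se + 1)
})

test_that("bleaching is absorbing", {
  gt <- simulate_trajectories(
    sim_config(box_size = 10, density = 0.5, tau_bleach_true = 0.2,
               n_frames = 50, rng_seed = 9),
    quick_optics(), sub_steps = 1)
  per_mol <- split(gt$tracks$state, gt$tracks$molecule_id)
  for (st in per_mol) {
    first_bleached <- match("bleached", st)
    if (!is.na(first_bleached)) {
      expect_true(all(st[first_bleached:length(st)] == "bleached"))
    }
  }
  expect_gt(sum(gt$tracks$state == "bleached"), 0)
})

test_that("noiseless rendering conserves photons and obeys the evanescent decay", {
  opt <- optics_model(exposure = 0.5, frame_interval = 0.5,
                      evanescent_depth = 100)
  at0 <- render_static_spot(5, 5, 0, opt, box_size = 10)$frames[[1]]
  expect_equal(sum(at0 - opt$baseline), opt$photon_rate * opt$exposure * opt$gain,
               tolerance = 1e-3)
  atd <- render_static_spot(5, 5, 100, opt, box_size = 10)$frames[[1]]
  expect_equal(sum(atd - opt$baseline),
               opt$photon_rate * opt$exposure * opt$gain / exp(1),
               tolerance = 1e-3)
})

test_that("long-exposure blur suppresses the free-molecule peak response >= 5x", {
  opt <- optics_model(exposure = 0.5, frame_interval = 0.5)
  static_peak <- max(render_static_spot(5, 5, 0, opt, 10)$frames[[1]] -
                       opt$baseline)
  set.seed(11)
  free_peaks <- replicate(10, {
    gt <- simulate_trajectories(
      sim_config(box_size = 10, density = 0, d_free = 2.5, n_frames = 1,
                 rng_seed = sample.int(1e6, 1)),
      opt, sub_steps = 20, n_molecules = 1, p_bound0 = 0)
    max(render_movie(gt, opt, noise = FALSE)$frames[[1]] - opt$baseline)
  })
  expect_true(all(static_peak / free_peaks >= 5))
})

test_that("rendered background level matches the configured baseline", {
  gt <- simulate_trajectories(
    sim_config(box_size = 5, density = 0, n_frames = 2, rng_seed = 1),
    quick_optics(), sub_steps = 10, n_molecules = 0)
  mv <- render_movie(gt, quick_optics(baseline = 100, read_noise_sd = 2))
  m <- mean(mv$frames[[1]])
  n <- length(mv$frames[[1]])
  expect_lt(abs(m - 100), 4 * 2 / sqrt(n))
})

test_that("activation population hits the Hill probabilities at the anchors", {
  # at the half-maximal density, activation probability is max_resp / 2
  pop <- simulate_activation_population(0.3, ec50 = 0.3, hill = 2,
                                        max_resp = 0.8, n_cells = 4000,
                                        rng_seed = 2)
  expect_lt(abs(mean(pop$activated) - 0.4), 3 * sqrt(0.4 * 0.6 / 4000))
  # far above the EC50 the probability saturates at max_resp
  pop_hi <- simulate_activation_population(3000, ec50 = 0.3, hill = 2,
                                           max_resp = 0.8, n_cells = 4000,
                                           rng_seed = 3)
  expect_lt(abs(mean(pop_hi$activated) - 0.8), 3 * sqrt(0.8 * 0.2 / 4000))
  expect_error(simulate_activation_population(1, 0.3, hill = -1), "hill")
})

test_that("event-stream generator respects degenerate condensation rates", {
  st0 <- simulate_event_streams(10, 8, p_condensate = 0, background_rate = 0,
                                rng_seed = 4)
  er0 <- compute_event_ratios(st0$events, st0$condensates)
  expect_true(all(er0$ratio[!is.na(er0$ratio)] == 0))
  st1 <- simulate_event_streams(10, 8, p_condensate = 1, background_rate = 0,
                                rng_seed = 4)
  er1 <- compute_event_ratios(st1$events, st1$condensates, window = Inf)
  expect_true(all(er1$ratio[!is.na(er1$ratio)] == 1))
})

test_that("truncated height sampling stays inside the contour and orders by tether", {
  set.seed(6)
  short <- sample_tether_heights(tether_design(16, 0), 500)
  med <- sample_tether_heights(tether_design(16, 19), 500)
  lng <- sample_tether_heights(tether_design(16, 59), 500)
  expect_true(all(short == 0))
  expect_true(all(med >= 0 & med <= 19 * 0.6))
  expect_true(all(lng >= 0 & lng <= 59 * 0.6))
  expect_lt(mean(med), mean(lng))
})
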