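test_that("mobility gate separates bound from free tracks", {
  opt <- optics_model(exposure = 0.5, frame_interval = 0.5)
  gt_b <- simulate_trajectories(
    sim_config(box_size = 20, d_free = 2.5, d_bound = 0.01, n_frames = 40,
               rng_seed = 1),
    opt, sub_steps = 1, n_molecules = 10, p_bound0 = 1)
  bound_tracks <- classify_bound(truth_tracks(gt_b), frame_interval = 0.5)
  # every bound molecule stays classified bound for its whole lifetime
  expect_equal(sort(unique(bound_tracks$track_id)), 1:10)
  expect_equal(nrow(bound_tracks), nrow(gt_b$tracks))

  gt_f <- simulate_trajectories(
    sim_config(box_size = 20, d_free = 2.5, d_bound = 0.01, n_frames = 40,
               rng_seed = 2),
    opt, sub_steps = 1, n_molecules = 10, p_bound0 = 0)
  free_tracks <- classify_bound(truth_tracks(gt_f), frame_interval = 0.5)
  expect_equal(nrow(free_tracks), 0)

  empty <- classify_bound(truth_tracks(gt_f)[0, ], frame_interval = 0.5)
  expect_equal(nrow(empty), 0)
})

test_that("censored exponential fit recovers the ~50 s benchmark within 10%", {
  rec <- simulate_dwell_records(1000, tau_off = 50, lapse = 10, rng_seed = 3)
  f <- fit_dwell_distribution(rec, lapse = 10)
  expect_lt(abs(f$tau_off - 50) / 50, 0.10)
  expect_false(f$lower_bound)
})

test_that("photobleach correction undoes a known bleach rate", {
  rec <- simulate_dwell_records(2000, tau_off = 50, tau_bleach = 300,
                                lapse = 10, rng_seed = 4)
  f <- fit_dwell_distribution(rec, lapse = 10, tau_bleach = 300)
  expect_lt(abs(f$tau_off - 50) / 50, 0.10)
  # the observed time constant is shorter than the corrected one
  expect_lt(f$tau_obs, f$tau_off)
  # with tau_bleach = Inf the corrected and observed values coincide
  f_inf <- fit_dwell_distribution(rec, lapse = 10, tau_bleach = Inf)
  expect_equal(f_inf$tau_obs, f_inf$tau_off)
})

test_that("correction only lengthens: tau_off >= tau_obs over a rate grid", {
  for (tau_true in c(20, 50, 100)) {
    rec <- simulate_dwell_records(500, tau_off = tau_true, tau_bleach = 300,
                                  lapse = 10, rng_seed = round(tau_true))
    f <- fit_dwell_distribution(rec, lapse = 10, tau_bleach = 300)
    expect_gte(f$tau_off, f$tau_obs)
    expect_lt(abs(f$tau_off - tau_true) / tau_true, 0.10)
  }
})

test_that("tracking loss yields a flagged lower bound exceeding the loss time", {
  rec <- simulate_dwell_records(500, tau_off = 240, censor_time = 120,
                                lapse = 10, rng_seed = 5)
  f <- fit_dwell_distribution(rec, lapse = 10)
  expect_true(f$lower_bound)
  expect_gte(f$tau_off, 120)
})

test_that("degenerate bleach calibration is flagged, not silently corrected", {
  rec <- simulate_dwell_records(300, tau_off = 100, lapse = 10, rng_seed = 6)
  # bleach calibration faster than the observed decay: correction undefined
  f <- fit_dwell_distribution(rec, lapse = 10, tau_bleach = 20)
  expect_true(f$lower_bound)
  expect_identical(f$tau_off, Inf)
})

test_that("all-censored input produces a lower-bound-only fit", {
  rec <- tibble::tibble(duration_s = rep(120, 30), censored = TRUE)
  f <- suppressWarnings(fit_dwell_distribution(rec, lapse = 10))
  expect_true(f$lower_bound)
  expect_identical(f$tau_obs, Inf)
  expect_equal(f$ci95[1], 120)
})

test_that("per-illuminated-second bleach times convert through the duty cycle", {
  rec <- simulate_dwell_records(1000, tau_off = 50, tau_bleach = 6000,
                                lapse = 10, rng_seed = 7)
  # 300 s of illuminated time at a 0.5 s / 10 s duty cycle = 6000 s of movie
  f_wall <- fit_dwell_distribution(rec, lapse = 10, tau_bleach = 6000)
  f_illum <- fit_dwell_distribution(rec, lapse = 10, tau_bleach = 300,
                                    exposure = 0.5)
  expect_equal(f_wall$tau_off, f_illum$tau_off, tolerance = 1e-10)
})

test_that("fraction-bound estimator hits the trivial and benchmark cases", {
  cf <- simulate_cell_frames(1, rng_seed = 8)
  # with spot counting the all-bound identity is exact; the intensity-based
  # denominator carries photon-noise at the percent level
  est_spots <- estimate_fraction_bound(cf$long, cf$short, cf$footprint,
                                       count_mode = "spots")
  expect_equal(est_spots$fraction_bound, 1)
  est <- estimate_fraction_bound(cf$long, cf$short, cf$footprint)
  expect_gte(est$fraction_bound, 0.95)

  meds <- vapply(c(0.9, 0.3), function(tf) {
    fr <- vapply(1:30, function(i) {
      cfi <- simulate_cell_frames(tf, rng_seed = 100 * tf + i)
      suppressWarnings(
        estimate_fraction_bound(cfi$long, cfi$short, cfi$footprint)$fraction_bound)
    }, 0)
    stats::median(fr, na.rm = TRUE)
  }, 0)
  expect_gte(meds[1], 0.85)         # truth 0.9: median above 0.85
  expect_lt(abs(meds[2] - 0.30), 0.10)  # truth 0.3 recovered
})

test_that("fraction-bound is insensitive to ligand density across the regime", {
  meds <- vapply(c(0.02, 0.05, 0.1), function(rho) {
    fr <- vapply(1:20, function(i) {
      cfi <- simulate_cell_frames(0.5, density = rho,
                                  rng_seed = round(1e4 * rho) + i)
      suppressWarnings(
        estimate_fraction_bound(cfi$long, cfi$short, cfi$footprint)$fraction_bound)
    }, 0)
    stats::median(fr, na.rm = TRUE)
  }, 0)
  expect_true(all(abs(meds - 0.5) < 0.15))
})

test_that("dwell fit methods expose broom-style output", {
  rec <- simulate_dwell_records(200, tau_off = 50, lapse = 10, rng_seed = 9)
  f <- fit_dwell_distribution(rec, lapse = 10)
  expect_named(glance(f), c("tau_obs", "tau_off", "tau_bleach", "conf.low",
                            "conf.high", "n_events", "n_censored",
                            "lower_bound"))
  expect_equal(nrow(tidy(f)), 2)
  expect_s3_class(autoplot(f), "ggplot")
})
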