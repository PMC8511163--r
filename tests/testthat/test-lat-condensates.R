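test_that("a persistent synthetic condensate is found; a 3-frame one is filtered", {
  one <- tibble::tibble(t_start_s = 10, x_um = 5, y_um = 5,
                        lifetime_frames = 10L)
  mv <- render_condensate_movie(one, n_frames = 30)
  tracks <- detect_and_track_condensates(mv)
  expect_equal(nrow(tracks), 1)
  expect_gte(tracks$lifetime_frames, 9)

  short <- tibble::tibble(t_start_s = 10, x_um = 5, y_um = 5,
                          lifetime_frames = 3L)
  mv3 <- render_condensate_movie(short, n_frames = 30)
  expect_equal(nrow(detect_and_track_condensates(mv3, min_lifetime = 4)), 0)
  expect_equal(nrow(detect_and_track_condensates(mv3, min_lifetime = 3)), 1)
})

test_that("detection at realistic SNR has recall and precision >= 0.9", {
  set.seed(1)
  n <- 20
  cds <- tibble::tibble(
    t_start_s = runif(n, 0, 60),
    x_um = runif(n, 1, 9), y_um = runif(n, 1, 9),
    lifetime_frames = sample(4:10, n, replace = TRUE))
  # keep ground-truth condensates separated so identity is unambiguous
  mv <- render_condensate_movie(cds, n_frames = 60)
  det <- detect_and_track_condensates(mv)
  matched <- vapply(seq_len(n), function(i) {
    any(sqrt((det$x_um - cds$x_um[i])^2 + (det$y_um - cds$y_um[i])^2) < 0.5)
  }, logical(1))
  true_pos <- vapply(seq_len(nrow(det)), function(j) {
    any(sqrt((det$x_um[j] - cds$x_um)^2 + (det$y_um[j] - cds$y_um)^2) < 0.5)
  }, logical(1))
  expect_gte(mean(matched), 0.9)              # recall
  expect_gte(mean(true_pos), 0.9)             # precision
})

test_that("raising the persistence threshold never increases the count", {
  set.seed(2)
  cds <- tibble::tibble(t_start_s = runif(15, 0, 40),
                        x_um = runif(15, 1, 9), y_um = runif(15, 1, 9),
                        lifetime_frames = sample(2:12, 15, replace = TRUE))
  mv <- render_condensate_movie(cds, n_frames = 40)
  counts <- vapply(1:8, function(ml) {
    nrow(detect_and_track_condensates(mv, min_lifetime = ml))
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("per-cell event ratios recover the condensation probability", {
  st <- simulate_event_streams(30, 10, p_condensate = 0.6,
                               background_rate = 0, rng_seed = 3)
  er <- compute_event_ratios(st$events, st$condensates)
  expect_lt(abs(attr(er, "summary")$median - 0.6), 0.15)
})

test_that("cells without binding events are kept and flagged", {
  st <- simulate_event_streams(5, 0, p_condensate = 0,
                               background_rate = 2, rng_seed = 4)
  er <- compute_event_ratios(st$events, st$condensates)
  expect_true(all(er$flag == "no_binding_events"))
  expect_true(all(is.na(er$ratio)))
  expect_true(any(er$n_condensates > 0))
})

test_that("background condensates can push ratios above one", {
  st <- simulate_event_streams(20, 2, p_condensate = 1,
                               background_rate = 4, rng_seed = 5)
  er <- compute_event_ratios(st$events, st$condensates)
  expect_gt(max(er$ratio, na.rm = TRUE), 1)
})

test_that("rank-sum comparison matches the exact enumeration null for n <= 8", {
  set.seed(6)
  for (rep in 1:5) {
    a <- round(runif(6), 3); b <- round(runif(7), 3)
    got <- compare_groups(c(a, rep(0, 0)), b)
    # oracle: enumerate all assignments of the pooled sample
    p_exact <- exact_mw_p(a, b)
    expect_lt(abs(got$p_value - p_exact), 0.08)
    # U statistic from first principles
    u <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    expect_equal(got$u_statistic, u)
  }
})

test_that("clearly separated groups are strongly significant; identical are not", {
  set.seed(7)
  a <- pmax(rnorm(30, 0.6, 0.15), 0)
  b <- pmax(rnorm(30, 0.1, 0.08), 0)
  res <- compare_groups(a, b)
  expect_lt(res$p_value, 1e-3)
  expect_true(res$significance %in% c("***", "****"))
  same <- compare_groups(a, a)
  expect_equal(same$significance, "ns")
  expect_gt(same$p_value, 0.9)
})

test_that("one outlier barely moves the U statistic", {
  set.seed(8)
  a <- runif(20)
  b <- c(a[-1], 1e6)
  res <- compare_groups(a, b)
  expect_lt(abs(res$u_statistic - 20^2 / 2), 25)
  expect_equal(res$significance, "ns")
})

test_that("colocalization labels follow the radius and lag windows", {
  ev <- tibble::tibble(t_s = c(10, 10), x_um = c(2, 2), y_um = c(2, 2))
  cd <- tibble::tibble(t_start_s = c(15, 12), x_um = c(2.1, 7),
                       y_um = c(2.1, 2))
  lab <- colocalize_events(ev, cd)
  expect_true(all(lab$colocalized))
  # 5 um away and nothing nearby in time
  lab2 <- colocalize_events(ev[1, ], cd[2, , drop = FALSE])
  expect_false(lab2$colocalized)
  # condensate before the event does not count
  lab3 <- colocalize_events(tibble::tibble(t_s = 20, x_um = 2, y_um = 2),
                            tibble::tibble(t_start_s = 15, x_um = 2, y_um = 2))
  expect_false(lab3$colocalized)
})

test_that("colocalization on generated streams labels event-paired condensates", {
  st <- simulate_event_streams(10, 10, p_condensate = 0.5, rng_seed = 9)
  lab <- colocalize_events(st$events, st$condensates)
  truth <- st$events$event_id %in%
    st$condensates$from_event[!is.na(st$condensates$from_event)]
  # match within cells
  truth <- purrr::map_lgl(seq_len(nrow(st$events)), function(i) {
    any(st$condensates$cell_id == st$events$cell_id[i] &
          !is.na(st$condensates$from_event) &
          st$condensates$from_event == st$events$event_id[i])
  })
  expect_gte(mean(lab$colocalized == truth), 0.95)
})
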