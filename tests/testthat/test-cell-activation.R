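test_that("nfat scoring is exact on constructed compartments", {
  cell <- render_nfat_cell(nuc_cyt_ratio = 1, noise_sd = 0, rng_seed = 1)
  sc <- score_nfat(cell$image, cell$nucleus_mask, cell$cytosol_mask, 100)
  expect_equal(sc$nfat_ratio, 1)
  expect_false(sc$activated)   # strictly greater than one required

  cell2 <- render_nfat_cell(nuc_cyt_ratio = 2, rng_seed = 2)
  seg <- segment_nucleus_cytosol(cell2$image, cell2$footprint)
  expect_equal(seg$qc_flag, "ok")
  sc2 <- score_nfat(cell2$image, seg$nucleus_mask, seg$cytosol_mask, 100)
  expect_lt(abs(sc2$nfat_ratio - 2), 0.05)
  expect_true(sc2$activated)
})

test_that("cytosol at background level is flagged and excluded", {
  cell <- render_nfat_cell(cytosol_intensity = 0, nuc_cyt_ratio = 1,
                           noise_sd = 1, rng_seed = 3)
  sc <- score_nfat(cell$image, cell$nucleus_mask, cell$cytosol_mask, 100)
  expect_equal(sc$qc_flag, "cytosol_at_background")
  expect_true(is.na(sc$nfat_ratio))
})

test_that("empty or overlapping masks raise errors", {
  cell <- render_nfat_cell(rng_seed = 4)
  none <- matrix(FALSE, nrow(cell$image), ncol(cell$image))
  expect_error(score_nfat(cell$image, none, cell$cytosol_mask, 100), "non-empty")
  expect_error(score_nfat(cell$image, cell$footprint, cell$cytosol_mask, 100),
               "disjoint")
})

test_that("scoring is invariant under affine intensity rescaling", {
  cell <- render_nfat_cell(nuc_cyt_ratio = 1.8, rng_seed = 5)
  sc1 <- score_nfat(cell$image, cell$nucleus_mask, cell$cytosol_mask, 100)
  sc2 <- score_nfat(3 * cell$image + 40, cell$nucleus_mask, cell$cytosol_mask,
                    3 * 100 + 40)
  expect_equal(sc1$nfat_ratio, sc2$nfat_ratio, tolerance = 1e-12)
})

test_that("segmentation finds nuclei with IoU >= 0.8 in both contrast directions", {
  for (ratio in c(2, 0.5)) {
    cell <- render_nfat_cell(nuc_cyt_ratio = ratio, rng_seed = 10 + ratio)
    seg <- segment_nucleus_cytosol(cell$image, cell$footprint)
    expect_equal(seg$qc_flag, "ok")
    iou <- sum(seg$nucleus_mask & cell$nucleus_mask) /
      sum(seg$nucleus_mask | cell$nucleus_mask)
    expect_gte(iou, 0.8)
  }
})

test_that("structureless or edge-touching cells are excluded by qc", {
  img <- matrix(100 + rnorm(80 * 80, 0, 8), 80)
  fp <- matrix(FALSE, 80, 80); fp[20:60, 20:60] <- TRUE
  expect_equal(segment_nucleus_cytosol(img, fp)$qc_flag, "no_nucleus")

  edge_cell <- render_nfat_cell(nucleus_offset_px = c(19, 0), rng_seed = 6)
  seg <- segment_nucleus_cytosol(edge_cell$image, edge_cell$footprint)
  expect_true(seg$qc_flag %in% c("nucleus_touches_edge", "no_nucleus"))
})

test_that("Hill fit recovers the half-maximal density in the printed band", {
  pop <- simulate_activation_population(c(0.05, 0.1, 0.3, 1, 3), ec50 = 0.3,
                                        hill = 2, max_resp = 0.9,
                                        n_cells = 200, rng_seed = 7)
  f <- fit_dose_response(pop)
  expect_true(f$converged)
  expect_gte(f$ec50, 0.2)
  expect_lte(f$ec50, 0.4)
  expect_true(f$ec50_ci95[1] <= f$ec50 && f$ec50 <= f$ec50_ci95[2])
})

test_that("noiseless curve points are recovered exactly", {
  dens <- c(0.05, 0.1, 0.3, 1, 3)
  p <- 0.8 * dens^2 / (dens^2 + 0.3^2)
  n <- 100000
  cells <- purrr::map_dfr(seq_along(dens), function(i) {
    k <- round(p[i] * n)
    tibble::tibble(density = dens[i],
                   activated = rep(c(TRUE, FALSE), c(k, n - k)))
  })
  f <- suppressWarnings(fit_dose_response(cells))
  expect_lt(abs(f$ec50 - 0.3) / 0.3, 0.01)
  expect_lt(abs(f$hill - 2), 0.05)
  expect_lt(abs(f$max_resp - 0.8), 0.01)
})

test_that("an inactive population yields a flagged fit without EC50", {
  cells <- tidyr::expand_grid(density = c(0.1, 1, 10),
                              cell = 1:60) |>
    dplyr::transmute(density, activated = FALSE)
  f <- suppressWarnings(fit_dose_response(cells))
  expect_equal(f$flag, "no_activation")
  expect_true(is.na(f$ec50))
})

test_that("EC50 scales linearly under a density unit change", {
  pop <- simulate_activation_population(c(0.05, 0.1, 0.3, 1, 3), ec50 = 0.3,
                                        hill = 2, max_resp = 0.9,
                                        n_cells = 300, rng_seed = 8)
  f1 <- fit_dose_response(pop)
  f2 <- fit_dose_response(dplyr::mutate(pop, density = density * 100))
  expect_equal(f2$ec50 / f1$ec50, 100, tolerance = 1e-6)
})

test_that("EC50 recovery is stable over seeded replicates with honest CIs", {
  hits <- 0; in_band <- numeric(50)
  for (i in 1:50) {
    pop <- simulate_activation_population(c(0.05, 0.1, 0.3, 1, 3), ec50 = 0.3,
                                          hill = 2, max_resp = 0.9,
                                          n_cells = 200, rng_seed = 1000 + i)
    f <- fit_dose_response(pop)
    in_band[i] <- f$ec50
    hits <- hits + (f$ec50_ci95[1] <= 0.3 && 0.3 <= f$ec50_ci95[2])
  }
  expect_lt(abs(stats::median(in_band) - 0.3) / 0.3, 0.15)
  expect_gte(hits / 50, 0.90)
})

test_that("potency ratios reproduce the 10x and 100x tether-length losses", {
  base <- simulate_activation_population(c(0.05, 0.1, 0.3, 1, 3), 0.3, 2, 0.9,
                                         200, rng_seed = 9)
  f0 <- fit_dose_response(base)
  for (fold in c(10, 100)) {
    weak <- simulate_activation_population(c(0.05, 0.1, 0.3, 1, 3) * fold,
                                           0.3 * fold, 2, 0.9, 200,
                                           rng_seed = 9 + fold)
    fw <- fit_dose_response(weak)
    pr <- potency_ratio(f0, fw)
    expect_lt(abs(log(pr$ratio / fold)), log(2))  # within 2-fold
    expect_false(pr$one_sided)
  }
  same <- potency_ratio(f0, f0)
  expect_equal(same$ratio, 1)
})

test_that("dose-response accessors behave", {
  pop <- simulate_activation_population(c(0.1, 0.3, 1), 0.3, 2, 0.9, 100,
                                        rng_seed = 10)
  f <- suppressWarnings(fit_dose_response(pop))
  expect_equal(tidy(f)$term, c("ec50", "hill", "max_resp"))
  expect_true(is.numeric(glance(f)$loglik))
  expect_s3_class(autoplot(f), "ggplot")
})
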