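#' Fit a Hill dose-response curve to per-cell activation calls
#'
#' Aggregates activated fractions per ligand density and fits the Hill model
#' \deqn{f(\rho) = f_{max} \frac{\rho^h}{\rho^h + EC_{50}^h}}
#' by binomial maximum likelihood. The half-maximal density EC50 gets a 95%
#' profile-likelihood confidence interval; the Hill coefficient is bounded
#' to \[0.5, 4\] for stability at desk-scale cell counts, and `max_resp` may
#' be fixed (e.g. to a reference ligand's plateau) to extrapolate fits for
#' weak ligands that never saturate.
#'
#' @param cells Tibble with `density` and logical `activated` (one row per
#'   cell), e.g. from [simulate_activation_population()] or assembled from
#'   [score_nfat()] calls.
#' @param max_resp Fix the maximal response at this value instead of
#'   fitting it.
#' @param hill_bounds Lower/upper bounds for the Hill coefficient.
#' @return A `dose_response_fit`: `ec50`, `hill`, `max_resp`, `ec50_ci95`,
#'   `points` (per-density fractions with SEs and cell counts),
#'   `converged`, `flag`, `loglik`.
#' @examples
#' pop <- simulate_activation_population(c(0.05, 0.1, 0.3, 1, 3), 0.3,
#'                                       hill = 2, max_resp = 0.9,
#'                                       n_cells = 100, rng_seed = 2)
#' fit_dose_response(pop)
#' @export
fit_dose_response <- function(cells, max_resp = NULL,
                              hill_bounds = c(0.5, 4)) {
  stopifnot(all(c("density", "activated") %in% names(cells)))
  cells <- dplyr::filter(cells, !is.na(.data$activated))
  points <- cells |>
    dplyr::group_by(density = .data$density) |>
    dplyr::summarise(n_cells = dplyr::n(), n_act = sum(.data$activated),
                     .groups = "drop") |>
    dplyr::mutate(fraction = .data$n_act / .data$n_cells,
                  se = sqrt(.data$fraction * (1 - .data$fraction) /
                              .data$n_cells))
  if (nrow(points) < 3) abort("need >= 3 distinct densities")
  if (any(points$n_cells < 50)) {
    warn("fewer than 50 cells at some densities; fractions will be noisy")
  }
  if (all(points$n_act == 0)) {
    return(structure(list(ec50 = NA_real_, hill = NA_real_,
                          max_resp = NA_real_, ec50_ci95 = c(max(points$density), Inf),
                          points = points, converged = FALSE,
                          flag = "no_activation", loglik = NA_real_),
                     class = "dose_response_fit"))
  }

  nll <- function(log_ec50, h, fmax) {
    p <- fmax * points$density^h / (points$density^h + exp(log_ec50)^h)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(points$n_act * log(p) + (points$n_cells - points$n_act) * log(1 - p))
  }
  fix_fmax <- !is.null(max_resp)
  obj <- function(par) {
    nll(par[1], par[2], if (fix_fmax) max_resp else stats::plogis(par[3]))
  }
  start <- c(log(stats::weighted.mean(points$density, points$fraction *
                                        (1 - points$fraction) + 1e-3)),
             1.5, stats::qlogis(min(max(max(points$fraction), 0.05), 0.99)))
  npar <- if (fix_fmax) 2L else 3L
  op <- optim(start[seq_len(npar)], obj, method = "L-BFGS-B",
              lower = c(log(min(points$density)) - 5, hill_bounds[1], -6),
              upper = c(log(max(points$density)) + 5, hill_bounds[2], 6)[seq_len(npar)])
  ec50 <- exp(op$par[1]); hill <- op$par[2]
  fmax <- if (fix_fmax) max_resp else stats::plogis(op$par[3])

  # profile-likelihood 95% CI for EC50
  prof <- function(l_ec50) {
    o <- optim(op$par[-1], function(p) {
      nll(l_ec50, p[1], if (fix_fmax) max_resp else stats::plogis(p[2]))
    }, method = "L-BFGS-B",
    lower = c(hill_bounds[1], -6)[seq_len(npar - 1L)],
    upper = c(hill_bounds[2], 6)[seq_len(npar - 1L)])
    o$value
  }
  cut <- op$value + qnorm(0.975)^2 / 2
  ci <- tryCatch({
    lo <- uniroot(function(l) prof(l) - cut, c(op$par[1] - 6, op$par[1]),
                  extendInt = "no")$root
    hi <- uniroot(function(l) prof(l) - cut, c(op$par[1], op$par[1] + 6),
                  extendInt = "no")$root
    exp(c(lo, hi))
  }, error = function(e) c(NA_real_, NA_real_))

  structure(list(ec50 = ec50, hill = hill, max_resp = fmax,
                 ec50_ci95 = ci, points = points,
                 converged = op$convergence == 0, flag = "ok",
                 loglik = -op$value),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!is.na(x$ec50)) {
    cat(sprintf("<dose_response_fit> EC50 = %.3g /um^2 (95%% CI %.3g-%.3g), hill %.2f, max %.2f\n",
                x$ec50, x$ec50_ci95[1], x$ec50_ci95[2], x$hill, x$max_resp))
  } else {
    cat(sprintf("<dose_response_fit> not fitted (%s)\n", x$flag))
  }
  invisible(x)
}

#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble::tibble(term = c("ec50", "hill", "max_resp"),
                 estimate = c(x$ec50, x$hill, x$max_resp),
                 conf.low = c(x$ec50_ci95[1], NA, NA),
                 conf.high = c(x$ec50_ci95[2], NA, NA))
}

#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble::tibble(ec50 = x$ec50, hill = x$hill, max_resp = x$max_resp,
                 ec50_low = x$ec50_ci95[1], ec50_high = x$ec50_ci95[2],
                 n_cells = sum(x$points$n_cells), converged = x$converged,
                 flag = x$flag, loglik = x$loglik)
}

#' @export
autoplot.dose_response_fit <- function(object, ...) {
  pts <- object$points
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$density, .data$fraction)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(.data$fraction - .data$se, 0),
                                          ymax = pmin(.data$fraction + .data$se, 1))) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression("ligand density (" * mu * m^-2 * ")"),
                  y = "fraction of activated cells")
  if (!is.na(object$ec50)) {
    p <- p + ggplot2::geom_function(
      fun = function(rho) {
        object$max_resp * rho^object$hill /
          (rho^object$hill + object$ec50^object$hill)
      }, colour = "steelblue") +
      ggplot2::geom_vline(xintercept = object$ec50, linetype = 2,
                          colour = "grey40")
  }
  p
}

#' Potency ratio between two fitted dose-response curves
#'
#' Ratio of half-maximal densities `ec50_b / ec50_a` — how many times more
#' ligand the second condition needs for the same response — with a
#' confidence interval propagated on the log scale from the two profile
#' CIs. If either EC50 is only bounded from below the ratio is reported
#' one-sided.
#'
#' @param fit_a,fit_b `dose_response_fit` objects (a = reference).
#' @return One-row tibble: `ratio`, `conf.low`, `conf.high`, `one_sided`.
#' @export
potency_ratio <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "dose_response_fit"),
            inherits(fit_b, "dose_response_fit"))
  one_sided <- fit_a$flag != "ok" || fit_b$flag != "ok"
  if (is.na(fit_a$ec50) || (is.na(fit_b$ec50) && is.na(fit_b$ec50_ci95[1]))) {
    abort("both fits must have an EC50 estimate or lower bound")
  }
  if (is.na(fit_b$ec50)) {
    # b never activated: EC50_b is lower-bounded, ratio is one-sided
    return(tibble::tibble(ratio = NA_real_,
                          conf.low = fit_b$ec50_ci95[1] / fit_a$ec50,
                          conf.high = Inf, one_sided = TRUE))
  }
  ratio <- fit_b$ec50 / fit_a$ec50
  se_log <- function(f) {
    if (any(is.na(f$ec50_ci95))) return(NA_real_)
    (log(f$ec50_ci95[2]) - log(f$ec50_ci95[1])) / (2 * qnorm(0.975))
  }
  s <- sqrt(se_log(fit_a)^2 + se_log(fit_b)^2)
  ci <- exp(log(ratio) + c(-1, 1) * qnorm(0.975) * s)
  tibble::tibble(ratio = ratio, conf.low = ci[1], conf.high = ci[2],
                 one_sided = one_sided)
}
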