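#' Build multi-delay step-size distributions from tracks
#'
#' For each requested delay `tau = k` frame intervals, collects the radial
#' displacement of every pair of localisations `k` frames apart within a
#' track (overlapping windows, the common convention, which maximises the
#' data; the fit corrects the confidence interval for the induced
#' correlation).
#'
#' @param tracks Track tibble (`track_id`, `frame`, `x_um`, `y_um`).
#' @param delays Delays in seconds; each must be a positive integer multiple
#'   of `frame_interval`.
#' @param frame_interval Seconds between frames.
#' @return A `step_size_data` object: tibble `delay_s`, `r_um` with the
#'   total step count in `attr(, "n_steps")`.
#' @examples
#' tr <- tibble::tibble(track_id = 1, frame = 0:1,
#'                      x_um = c(0, 3), y_um = c(0, 4))
#' build_step_distributions(tr, delays = 0.02, frame_interval = 0.02)
#' @export
build_step_distributions <- function(tracks, delays, frame_interval) {
  .assert_scalar_pos(frame_interval, "frame_interval")
  k_frames <- delays / frame_interval
  if (any(abs(k_frames - round(k_frames)) > 1e-8) || any(k_frames < 1)) {
    abort("every delay must be a positive integer multiple of `frame_interval`")
  }
  k_frames <- as.integer(round(k_frames))
  if (is.unsorted(delays, strictly = TRUE)) {
    abort("`delays` must be strictly increasing")
  }
  by_track <- split(tracks[c("frame", "x_um", "y_um")], tracks$track_id)
  out <- purrr::map_dfr(seq_along(delays), function(di) {
    k <- k_frames[di]
    purrr::imap_dfr(by_track, function(tr, id) {
      o <- order(tr$frame)
      fr <- tr$frame[o]; x <- tr$x_um[o]; y <- tr$y_um[o]
      # match frame f with frame f + k (robust to gaps)
      j <- match(fr + k, fr)
      ok <- !is.na(j)
      if (!any(ok)) return(NULL)
      tibble::tibble(delay_s = delays[di], k_frames = k, track_id = id,
                     r_um = sqrt((x[j[ok]] - x[ok])^2 + (y[j[ok]] - y[ok])^2))
    })
  })
  structure(out, class = c("step_size_data", class(out)),
            n_steps = nrow(out), frame_interval = frame_interval)
}

#' Fit the Brownian step-size model to multi-delay displacement data
#'
#' Simultaneously fits all delay distributions with the single-species 2-D
#' Brownian step-size density
#' \deqn{\rho(r, \tau; D) = \frac{r}{2 D \tau} \exp\!\left(-\frac{r^2}{4 D \tau}\right),}
#' whose joint maximum-likelihood estimate has the closed form
#' \eqn{\hat D = \sum_i r_i^2 / (4 \tau_i) / N}. The 95% confidence
#' interval uses a cluster-robust (per-track sandwich) standard error when
#' 10 or more tracks contribute, which accounts for the correlation between
#' overlapping windows and between delays; with fewer tracks it falls back
#' to the Fisher-information form `SE = D / sqrt(N_eff)` with an effective
#' sample size correction for overlap (steps at a `k`-frame delay counted
#' as `n/k` independent observations).
#'
#' An optional static localisation-error term (`E[r^2] = 4 D tau +
#' 4 sigma_loc^2`) can be co-fitted; it is off by default since the base
#' model carries no error term.
#'
#' @param data A `step_size_data` from [build_step_distributions()].
#' @param method `"mle"` (default) or `"wls"` (weighted least squares on
#'   binned densities; cross-check route).
#' @param fit_sigma_loc Also fit a localisation-error SD (um)?
#' @param n_bins Histogram bins per delay for `method = "wls"`.
#' @return A `diffusion_fit` object with elements `D` (um^2/s), `ci95`,
#'   `se`, `sigma_loc`, `n_steps`, `n_eff`, `method`, `data`.
#' @examples
#' set.seed(1)
#' r <- sqrt(rexp(2000, 1 / (4 * 2.5 * 0.02)))  # exact Brownian steps
#' d <- tibble::tibble(delay_s = 0.02, k_frames = 1L, r_um = r)
#' d <- structure(d, class = c("step_size_data", class(d)), n_steps = nrow(d))
#' fit_brownian(d)
#' @export
fit_brownian <- function(data, method = c("mle", "wls"),
                         fit_sigma_loc = FALSE, n_bins = 60) {
  method <- match.arg(method)
  stopifnot(inherits(data, "step_size_data"))
  if (nrow(data) == 0L || all(data$r_um <= 0)) {
    abort("no positive displacements to fit")
  }
  if (nrow(data) < 1000) {
    warn(sprintf("only %d steps; >= 1000 recommended for a stable fit", nrow(data)))
  }
  if (!"k_frames" %in% names(data)) data$k_frames <- 1L

  n_eff <- sum(tapply(data$r_um, data$delay_s, length) /
                 tapply(data$k_frames, data$delay_s, function(k) k[1]))
  sigma_loc <- 0

  if (method == "mle" && !fit_sigma_loc) {
    D <- sum(data$r_um^2 / (4 * data$delay_s)) / nrow(data)
  } else if (method == "mle") {
    nll <- function(p) {
      D <- exp(p[1]); s2 <- exp(p[2])
      v <- 4 * D * data$delay_s + 4 * s2      # E[r^2] per delay
      -sum(log(2 * data$r_um / v) - data$r_um^2 / v)
    }
    D0 <- sum(data$r_um^2 / (4 * data$delay_s)) / nrow(data)
    op <- optim(c(log(D0), log(1e-4)), nll, method = "Nelder-Mead")
    D <- exp(op$par[1]); sigma_loc <- sqrt(exp(op$par[2]))
  } else {
    # weighted least squares on binned empirical densities, all delays jointly
    binned <- data |>
      dplyr::group_by(.data$delay_s) |>
      dplyr::group_map(function(g, key) {
        h <- graphics::hist(g$r_um, breaks = n_bins, plot = FALSE)
        tibble::tibble(delay_s = key$delay_s, r = h$mids, dens = h$density,
                       w = pmax(h$counts, 1))
      }) |> dplyr::bind_rows()
    sse <- function(logD) {
      D <- exp(logD)
      mu <- with(binned, r / (2 * D * delay_s) * exp(-r^2 / (4 * D * delay_s)))
      sum(binned$w * (binned$dens - mu)^2)
    }
    D0 <- sum(data$r_um^2 / (4 * data$delay_s)) / nrow(data)
    D <- exp(optimize(sse, log(D0) + c(-2, 2))$minimum)
  }

  # cluster-robust SE by track for the ratio estimator when enough tracks
  se <- D / sqrt(n_eff)
  crit <- qnorm(0.975)
  if ("track_id" %in% names(data) && method == "mle" && !fit_sigma_loc) {
    g <- dplyr::group_by(tibble::as_tibble(data), .data$track_id) |>
      dplyr::summarise(s = sum(.data$r_um^2 / (4 * .data$delay_s)),
                       m = dplyr::n(), .groups = "drop")
    G <- nrow(g)
    if (G >= 10) {
      se <- sqrt(G / (G - 1) * sum((g$s - D * g$m)^2)) / sum(g$m)
      crit <- stats::qt(0.975, df = G - 1)
    }
  }
  structure(list(D = D, se = se, ci95 = D + c(-1, 1) * crit * se,
                 sigma_loc = sigma_loc, n_steps = nrow(data), n_eff = n_eff,
                 method = method, delays = sort(unique(data$delay_s)),
                 data = data),
            class = "diffusion_fit")
}

#' Brownian step-size probability density
#'
#' The single-species 2-D Brownian radial step density
#' `r / (2 D tau) * exp(-r^2 / (4 D tau))`; integrates to 1 over `r >= 0`.
#'
#' @param r Radial displacement, micrometres.
#' @param tau Delay, seconds.
#' @param D Diffusion coefficient, um^2/s.
#' @return Density values.
#' @export
dstep_brownian <- function(r, tau, D) {
  r / (2 * D * tau) * exp(-r^2 / (4 * D * tau))
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.4g um^2/s (95%% CI %.4g-%.4g), n = %d steps (%s)\n",
              x$D, x$ci95[1], x$ci95[2], x$n_steps, x$method))
  invisible(x)
}

#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble::tibble(term = "D", estimate = x$D, std.error = x$se,
                 conf.low = x$ci95[1], conf.high = x$ci95[2])
}

#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(D = x$D, se = x$se, conf.low = x$ci95[1],
                 conf.high = x$ci95[2], sigma_loc = x$sigma_loc,
                 n_steps = x$n_steps, n_eff = x$n_eff, method = x$method)
}

#' @export
autoplot.diffusion_fit <- function(object, ...) {
  df <- tibble::as_tibble(object$data)
  grid <- df |>
    dplyr::group_by(.data$delay_s) |>
    dplyr::reframe(r = seq(0, max(.data$r_um), length.out = 200)) |>
    dplyr::mutate(dens = dstep_brownian(.data$r, .data$delay_s, object$D))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_um)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$r, y = .data$dens),
                       colour = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(.data$delay_s), scales = "free",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "step size r (um)", y = "density",
                  title = sprintf("Brownian fit: D = %.3f um^2/s", object$D))
}
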