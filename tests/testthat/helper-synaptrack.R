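# shared fixture builders (all synthetic, generated at test time)

quick_optics <- function(...) {
  optics_model(exposure = 0.02, frame_interval = 0.02, ...)
}

# exact draws from the Brownian radial step density: r^2 ~ Exp(mean 4 D tau)
draw_brownian_steps <- function(n, D, tau) {
  sqrt(rexp(n, rate = 1 / (4 * D * tau)))
}

# step_size_data built directly from exact draws (bypasses tracking)
make_step_data <- function(n_per_delay, D, delays) {
  out <- purrr::map_dfr(delays, function(tau) {
    tibble::tibble(delay_s = tau,
                   k_frames = as.integer(round(tau / delays[1])),
                   r_um = draw_brownian_steps(n_per_delay, D, tau))
  })
  structure(out, class = c("step_size_data", class(out)),
            n_steps = nrow(out), frame_interval = delays[1])
}

# static multi-spot track table
make_static_tracks <- function(positions, n_frames, frame_interval = 0.5) {
  purrr::imap_dfr(positions, function(p, i) {
    tibble::tibble(track_id = i, frame = 0:(n_frames - 1),
                   t_s = (0:(n_frames - 1)) * frame_interval,
                   x_um = p[1], y_um = p[2], intensity = 1)
  })
}

# exact-enumeration Mann-Whitney two-sided p-value (oracle for small n)
exact_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(pooled), n)
  r_obs <- sum(rank(pooled)[seq_len(n)])
  stats_all <- apply(idx, 2, function(s) sum(rank(pooled)[s]))
  mu <- mean(stats_all)
  mean(abs(stats_all - mu) >= abs(r_obs - mu) - 1e-9)
}
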