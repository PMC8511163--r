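#' Count photobleach steps in an intensity trace
#'
#' Piecewise-constant mean-shift change-point segmentation by binary
#' segmentation with a BIC-style penalty scaled by a robust noise estimate
#' (median absolute deviation of the first differences). Only downward mean
#' shifts larger than `min_step_sd` noise SDs count as bleach steps, so a
#' monovalent single-fluorophore particle yields exactly one step.
#'
#' @param trace Numeric intensity vector, or a tibble with an `intensity`
#'   column; must extend until the signal reaches background.
#' @param penalty Penalised-least-squares penalty; `NULL` for the default
#'   `3 * sigma^2 * log(n)`.
#' @param min_step_sd Minimum step height in noise SDs (default 3).
#' @return List with `n_steps`, `change_points` (frame indices, 1-based,
#'   first frame of each new segment), `step_sizes`, and `noise_sd`.
#' @examples
#' count_bleach_steps(c(rep(1000, 50), rep(0, 50)))
#' @export
count_bleach_steps <- function(trace, penalty = NULL, min_step_sd = 3) {
  if (is.data.frame(trace)) trace <- trace$intensity
  x <- as.numeric(trace)
  n <- length(x)
  if (n < 4) abort("trace must have at least 4 frames")
  sigma <- mad(diff(x)) / sqrt(2)
  sigma <- max(sigma, .Machine$double.eps)
  if (is.null(penalty)) penalty <- 3 * sigma^2 * log(n)

  cps <- sort(.binseg(x, 1L, n, penalty))
  # segment means between change points
  bounds <- c(1L, cps, n + 1L)
  means <- vapply(seq_len(length(bounds) - 1L), function(i) {
    mean(x[bounds[i]:(bounds[i + 1L] - 1L)])
  }, 0)
  steps <- diff(means)
  down <- steps < -min_step_sd * sigma
  list(n_steps = sum(down), change_points = cps[down],
       step_sizes = steps[down], noise_sd = sigma)
}

# recursive binary segmentation: best single mean-shift split of x[lo:hi];
# accept if the SSE reduction exceeds the penalty
.binseg <- function(x, lo, hi, penalty) {
  n <- hi - lo + 1L
  if (n < 4L) return(integer(0))
  seg <- x[lo:hi]
  cs <- cumsum(seg); tot <- cs[n]
  k <- seq_len(n - 1L)
  # SSE reduction of splitting after position k (constant-mean segments)
  red <- cs[k]^2 / k + (tot - cs[k])^2 / (n - k) - tot^2 / n
  red[c(1L, n - 1L)] <- -Inf  # keep >= 2 points on each side of a split
  best <- which.max(red)
  if (red[best] <= penalty) return(integer(0))
  cp <- lo + best  # first index of the right-hand segment
  c(.binseg(x, lo, cp - 1L, penalty), cp, .binseg(x, cp, hi, penalty))
}

#' Classify a particle population by photobleach step count
#'
#' Runs [count_bleach_steps()] on every trace and tabulates the fractions of
#' particles bleaching in one, two, and three-or-more steps with exact
#' (Clopper-Pearson) binomial confidence intervals. Used to establish
#' monovalency: a monomeric ligand population should be >99% single-step.
#'
#' @param traces Tibble with `trace_id`, `intensity` (and optionally `t_s`).
#' @param ... Passed to [count_bleach_steps()].
#' @return Tibble `n_steps_class` (`"0"`, `"1"`, `"2"`, `">=3"`), `n`,
#'   `fraction`, `conf.low`, `conf.high`.
#' @export
classify_population <- function(traces, ...) {
  stopifnot(is.data.frame(traces), nrow(traces) > 0)
  ids <- unique(traces$trace_id)
  if (length(ids) < 50) {
    warn(sprintf("only %d traces; >= 50 recommended for stable fractions",
                 length(ids)))
  }
  counts <- vapply(ids, function(id) {
    count_bleach_steps(traces$intensity[traces$trace_id == id], ...)$n_steps
  }, 0L)
  cls <- cut(counts, c(-Inf, 0, 1, 2, Inf), labels = c("0", "1", "2", ">=3"))
  ntot <- length(ids)
  purrr::map_dfr(levels(cls), function(lv) {
    k <- sum(cls == lv)
    ci <- .binom_ci(k, ntot)
    tibble::tibble(n_steps_class = lv, n = k, fraction = k / ntot,
                   conf.low = ci[1], conf.high = ci[2])
  })
}

# Clopper-Pearson exact binomial interval
.binom_ci <- function(k, n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lo, hi)
}

#' Probability of a sub-diffraction neighbour under Poisson placement
#'
#' For molecules placed as a spatial Poisson process at the given surface
#' density, the probability that a particle has at least one neighbour
#' within `radius` — i.e. that two molecules are closer than the diffraction
#' limit and appear as one spot — is `1 - exp(-density * pi * radius^2)`.
#' This sets the expected apparent multi-step fraction for a genuinely
#' monomeric population.
#'
#' @param density Molecules per square micrometre (>= 0).
#' @param radius Coincidence radius, micrometres (default 0.2, a typical
#'   diffraction-limited spot radius).
#' @return Probability in \[0, 1\].
#' @examples
#' coincidence_probability(0.06, 0.2)
#' @export
coincidence_probability <- function(density, radius = 0.2) {
  if (any(density < 0) || any(radius < 0)) {
    abort("`density` and `radius` must be non-negative")
  }
  1 - exp(-density * pi * radius^2)
}
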