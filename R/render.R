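#' Render a simulated trajectory set into a TIRF image stack
#'
#' Converts ground-truth trajectories into camera frames. Each unbleached
#' molecule contributes a Gaussian point-spread function integrated along its
#' sub-exposure path, so fast free molecules smear into a blur at long
#' exposure while bound molecules render as sharp spots — the contrast the
#' long-exposure bound-ligand imaging strategy exploits. Emission is
#' attenuated by the evanescent field, `exp(-height / evanescent_depth)`.
#' With `noise = TRUE`, photon shot noise is Poisson, multiplied by camera
#' gain, with additive Gaussian read noise on top of the constant baseline.
#'
#' The PSF is integrated exactly over each pixel (difference of Gaussian
#' CDFs), not sampled at pixel centres. Molecules whose stamp falls entirely
#' outside the field are clipped and counted in `attr(movie, "n_clipped")`.
#'
#' @param truth A `ground_truth` from [simulate_trajectories()] run with
#'   `sub_steps >= 10` (needed for converged motion blur).
#' @param optics An [optics_model()]; defaults to the one used in the
#'   simulation.
#' @param noise Add shot + read noise? `FALSE` gives the noiseless expected
#'   image (in counts).
#' @return A `movie` object: list of numeric matrices (one per frame,
#'   `[row, col]` = `[y, x]`, 0-based pixel origin top-left) with the optics
#'   model and metadata attached.
#' @examples
#' gt <- simulate_trajectories(sim_config(box_size = 5, density = 0.2,
#'                                        n_frames = 3, rng_seed = 2),
#'                             optics_model(exposure = 0.02, frame_interval = 0.02))
#' mv <- render_movie(gt)
#' dim(mv$frames[[1]])
#' @export
render_movie <- function(truth, optics = truth$optics, noise = TRUE) {
  stopifnot(inherits(truth, "ground_truth"))
  box <- truth$config$box_size
  npx <- as.integer(ceiling(box / optics$pixel_size))
  if (truth$n_molecules == 0L) {
    frames <- lapply(seq_len(truth$config$n_frames), function(i) {
      img <- matrix(0, npx, npx)
      if (noise) {
        matrix(rpois(length(img), img) * optics$gain + optics$baseline +
                 rnorm(length(img), 0, optics$read_noise_sd), npx)
      } else img + optics$baseline
    })
    return(structure(list(frames = frames, optics = optics,
                          metadata = list(seed = truth$seed, box_size = box,
                                          n_molecules = 0L)),
                     class = "movie", n_clipped = 0L))
  }
  if (is.null(truth$fine) || truth$sub_steps < 10) {
    abort("render_movie() needs a simulation with sub_steps >= 10 for motion blur")
  }
  frames <- vector("list", max(truth$fine$frame) + 1L)
  n_clipped <- 0L
  photons_per_sub <- optics$photon_rate * optics$exposure / truth$sub_steps

  fine_by_frame <- split(truth$fine, truth$fine$frame)
  for (fk in names(fine_by_frame)) {
    sub <- fine_by_frame[[fk]]
    sub <- sub[!sub$bleached, , drop = FALSE]
    img <- matrix(0, nrow = npx, ncol = npx)
    if (nrow(sub)) {
      w <- photons_per_sub * exp(-sub$height_nm / optics$evanescent_depth)
      res <- .stamp_psf(img, sub$x_um, sub$y_um, w,
                        optics$psf_sigma, optics$pixel_size)
      img <- res$img
      n_clipped <- n_clipped + res$clipped
    }
    if (noise) {
      img <- rpois(length(img), img) * optics$gain + optics$baseline +
        rnorm(length(img), 0, optics$read_noise_sd)
      img <- matrix(img, nrow = npx)
    } else {
      img <- img * optics$gain + optics$baseline
    }
    frames[[as.integer(fk) + 1L]] <- img
  }
  structure(list(frames = frames, optics = optics,
                 metadata = list(seed = truth$seed, box_size = box,
                                 n_molecules = truth$n_molecules)),
            class = "movie", n_clipped = n_clipped)
}

# add pixel-integrated Gaussian PSFs at (x, y) um with total photon weights w
.stamp_psf <- function(img, x, y, w, psf_sigma, pixel_size) {
  npx_r <- nrow(img); npx_c <- ncol(img)
  half <- ceiling(4 * psf_sigma / pixel_size)
  clipped <- 0L
  for (i in seq_along(x)) {
    cx <- x[i] / pixel_size   # 0-based continuous pixel coords
    cy <- y[i] / pixel_size
    c0 <- floor(cx) - half; c1 <- floor(cx) + half
    r0 <- floor(cy) - half; r1 <- floor(cy) + half
    cc <- max(c0, 0L):min(c1, npx_c - 1L)
    rr <- max(r0, 0L):min(r1, npx_r - 1L)
    if (cc[1] > cc[length(cc)] || rr[1] > rr[length(rr)] ||
        c1 < 0 || c0 > npx_c - 1L || r1 < 0 || r0 > npx_r - 1L) {
      clipped <- clipped + 1L
      next
    }
    s <- psf_sigma / pixel_size
    fx <- diff(pnorm(c(cc, cc[length(cc)] + 1L), mean = cx, sd = s))
    fy <- diff(pnorm(c(rr, rr[length(rr)] + 1L), mean = cy, sd = s))
    img[rr + 1L, cc + 1L] <- img[rr + 1L, cc + 1L] + w[i] * outer(fy, fx)
  }
  list(img = img, clipped = clipped)
}

#' @export
print.movie <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<movie> %d frames of %d x %d px (%.3g um/px)\n",
              length(x$frames), d[1], d[2], x$optics$pixel_size))
  invisible(x)
}

#' Render one static spot (calibration helper)
#'
#' Noise-free single-frame image of a stationary fluorophore, used for
#' detector calibration and for testing intensity-height relations.
#'
#' @param x_um,y_um Position in micrometres (0-based grid, origin top-left).
#' @param height_nm Fluorophore height above the interface.
#' @param optics An [optics_model()].
#' @param box_size Field side length, micrometres.
#' @param noise Add camera noise?
#' @return A single-frame `movie`.
#' @export
render_static_spot <- function(x_um, y_um, height_nm = 0,
                               optics = optics_model(), box_size = 10,
                               noise = FALSE) {
  npx <- as.integer(ceiling(box_size / optics$pixel_size))
  img <- matrix(0, npx, npx)
  w <- optics$photon_rate * optics$exposure *
    exp(-height_nm / optics$evanescent_depth)
  img <- .stamp_psf(img, x_um, y_um, w, optics$psf_sigma, optics$pixel_size)$img
  if (noise) {
    img <- matrix(rpois(length(img), img) * optics$gain + optics$baseline +
                    rnorm(length(img), 0, optics$read_noise_sd), npx)
  } else {
    img <- img * optics$gain + optics$baseline
  }
  structure(list(frames = list(img), optics = optics,
                 metadata = list(box_size = box_size)), class = "movie")
}
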