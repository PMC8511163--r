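#' Camera and illumination model for TIRF movie rendering
#'
#' Bundles the optical and camera parameters needed to turn simulated
#' fluorophore trajectories into realistic image stacks: pixel size,
#' point-spread-function width, exposure and frame timing, the evanescent
#' field decay length, and camera gain/noise.
#'
#' The evanescent TIRF field decays exponentially with height above the
#' glass-water interface, so a fluorophore at height `h` nm emits photons at
#' `photon_rate * exp(-h / evanescent_depth)` per second of illumination.
#' Camera noise parameters are not reported in typical experimental setups
#' at this level of detail; the defaults below describe a generic EMCCD-like
#' detector and are documented in the methods vignette.
#'
#' @param pixel_size Pixel edge length, micrometres per pixel.
#' @param psf_sigma Gaussian PSF standard deviation, micrometres.
#' @param exposure Exposure time per frame, seconds. Must not exceed
#'   `frame_interval`.
#' @param frame_interval Time between frame starts, seconds.
#' @param evanescent_depth Exponential decay length of the evanescent
#'   illumination field, nanometres.
#' @param gain Camera gain (counts per detected photon).
#' @param read_noise_sd Gaussian read noise standard deviation, counts.
#' @param photon_rate Expected photons per second from one fluorophore at
#'   height zero.
#' @param baseline Constant camera offset added to every pixel, counts.
#'
#' @return An object of class `optics_model` (a named list).
#' @examples
#' optics_model(exposure = 0.02, frame_interval = 0.02)
#' @export
optics_model <- function(pixel_size = 0.1067,
                         psf_sigma = 0.15,
                         exposure = 0.5,
                         frame_interval = 0.5,
                         evanescent_depth = 100,
                         gain = 1,
                         read_noise_sd = 2,
                         photon_rate = 5000,
                         baseline = 100) {
  .assert_scalar_pos(pixel_size, "pixel_size")
  .assert_scalar_pos(psf_sigma, "psf_sigma")
  .assert_scalar_pos(exposure, "exposure")
  .assert_scalar_pos(frame_interval, "frame_interval")
  .assert_scalar_pos(evanescent_depth, "evanescent_depth")
  .assert_scalar_pos(gain, "gain")
  .assert_scalar_pos(read_noise_sd, "read_noise_sd", strict = FALSE)
  .assert_scalar_pos(photon_rate, "photon_rate")
  .assert_scalar_pos(baseline, "baseline", strict = FALSE)
  if (exposure > frame_interval + 1e-12) {
    abort("`exposure` must not exceed `frame_interval`")
  }
  structure(
    list(pixel_size = pixel_size, psf_sigma = psf_sigma,
         exposure = exposure, frame_interval = frame_interval,
         evanescent_depth = evanescent_depth, gain = gain,
         read_noise_sd = read_noise_sd, photon_rate = photon_rate,
         baseline = baseline),
    class = "optics_model")
}

#' @export
print.optics_model <- function(x, ...) {
  cat("<optics_model>\n")
  cat(sprintf("  pixel %g um/px, PSF sigma %g um\n", x$pixel_size, x$psf_sigma))
  cat(sprintf("  exposure %g s / frame interval %g s\n", x$exposure, x$frame_interval))
  cat(sprintf("  evanescent depth %g nm, photon rate %g /s, gain %g\n",
              x$evanescent_depth, x$photon_rate, x$gain))
  invisible(x)
}

#' Ground-truth simulation parameters for the ligand simulator
#'
#' Describes one simulated field of membrane-tethered ligands: a square box
#' populated at a given surface density with molecules that diffuse in two
#' dimensions, stochastically switch between a fast free state and a slow
#' receptor-bound state, photobleach in a single step, and sit at a
#' tether-dependent height above the bilayer.
#'
#' Dwell times in the bound state are exponential with mean `tau_off_true`
#' and bleach times are exponential with mean `tau_bleach_true` counted in
#' illuminated time only. Defaults reproduce a fast-diffusing monovalent
#' Fab'-DNA ligand on a fluid supported lipid bilayer.
#'
#' @param box_size Side of the simulated square field, micrometres.
#' @param density Molecule surface density, molecules per square micrometre.
#' @param d_free Free-state diffusion coefficient, square micrometres per second.
#' @param d_bound Bound-state diffusion coefficient, same units; must be
#'   smaller than `d_free`.
#' @param k_on_app Apparent free-to-bound switching rate, per second.
#' @param tau_off_true Mean bound-state dwell time, seconds (`Inf` for
#'   permanently bound).
#' @param tau_bleach_true Mean single-step bleach time in illuminated
#'   seconds (`Inf` disables bleaching).
#' @param fluorophore_height_max Maximum fluorophore height above the
#'   bilayer (tether contour length), nanometres.
#' @param height_mean,height_sd Mean and spread of the truncated-Gaussian
#'   fluorophore height distribution on `[0, fluorophore_height_max]`, nm.
#' @param n_frames Number of frames to simulate.
#' @param rng_seed Integer seed recorded in the output.
#'
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(d_free = 2.49, n_frames = 100)
#' @export
sim_config <- function(box_size = 25,
                       density = 0.06,
                       d_free = 2.49,
                       d_bound = 0.01,
                       k_on_app = 0,
                       tau_off_true = Inf,
                       tau_bleach_true = Inf,
                       fluorophore_height_max = 0,
                       height_mean = 0,
                       height_sd = 0,
                       n_frames = 100,
                       rng_seed = 1L) {
  .assert_scalar_pos(box_size, "box_size")
  .assert_scalar_pos(density, "density", strict = FALSE)
  .assert_scalar_pos(d_free, "d_free", strict = FALSE)
  .assert_scalar_pos(d_bound, "d_bound", strict = FALSE)
  .assert_scalar_pos(k_on_app, "k_on_app", strict = FALSE)
  .assert_scalar_pos(tau_off_true, "tau_off_true", finite = FALSE)
  .assert_scalar_pos(tau_bleach_true, "tau_bleach_true", finite = FALSE)
  .assert_scalar_pos(fluorophore_height_max, "fluorophore_height_max", strict = FALSE)
  .assert_scalar_pos(height_mean, "height_mean", strict = FALSE)
  .assert_scalar_pos(height_sd, "height_sd", strict = FALSE)
  .assert_scalar_pos(n_frames, "n_frames")
  if (d_bound > d_free) abort("`d_bound` must not exceed `d_free`")
  structure(
    list(box_size = box_size, density = density, d_free = d_free,
         d_bound = d_bound, k_on_app = k_on_app,
         tau_off_true = tau_off_true, tau_bleach_true = tau_bleach_true,
         fluorophore_height_max = fluorophore_height_max,
         height_mean = height_mean, height_sd = height_sd,
         n_frames = as.integer(n_frames), rng_seed = as.integer(rng_seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %g x %g um box, density %g /um^2, %d frames, seed %d\n",
              x$box_size, x$box_size, x$density, x$n_frames, x$rng_seed))
  cat(sprintf("  D_free %g, D_bound %g um^2/s; k_on %g /s; tau_off %g s; tau_bleach %g s\n",
              x$d_free, x$d_bound, x$k_on_app, x$tau_off_true, x$tau_bleach_true))
  invisible(x)
}
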