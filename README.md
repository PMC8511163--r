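# synaptrack

Single-molecule and cell-level image analysis for membrane-tethered T cell
receptor (TCR) ligands, with a full synthetic-data generator so every stage
can be validated by parameter recovery.

## The scientific problem

Synthetic TCR agonists — antibody Fab′ fragments coupled to DNA oligos and
hybridised to a supported lipid bilayer (SLB) — let experimenters control a
ligand's binding epitope and the intermembrane spacing it allows at a
binding event. Characterising such ligands rests on a handful of
single-molecule TIRF measurements, all of which this package implements:

* **Diffusion / monovalency.** Freely diffusing ligands are tracked and
  their step-size distributions at several delays `τ` fitted jointly with
  the 2-D Brownian model

  ρ(r, τ; D) = r / (2Dτ) · exp(−r² / 4Dτ),

  whose joint MLE is the closed form D̂ = Σᵢ rᵢ²/(4τᵢ) / N. Monovalency is
  confirmed by change-point counting of photobleach steps and compared with
  the analytic coincidence probability 1 − exp(−ρπr²) that two molecules sit
  below the diffraction limit.
* **Binding kinetics.** Receptor-bound ligands are nearly immobile, so a
  long (500 ms) exposure resolves them while free ligands blur away. Dwell
  times observed at a 10 s lapse are fitted by interval-censored exponential
  maximum likelihood and corrected for photobleaching by additive rates,
  1/τ_off = 1/τ_obs − 1/τ_bleach; the fraction of ligands bound under a
  cell footprint is the ratio of bound (long-exposure) to total
  (short-exposure) ligands.
* **T cell activation.** NFAT reporter images are segmented into nucleus and
  cytosol; a cell is activated when the background-subtracted
  nucleus/cytosol ratio exceeds 1. Activated fractions versus ligand density
  are fitted with a Hill curve f(ρ) = f_max ρʰ/(ρʰ + EC50ʰ) by binomial
  maximum likelihood, giving half-maximal densities and potency ratios.
* **TCR-proximal signalling.** LAT condensates are detected, tracked, and
  filtered for persistence (≥ 4 frames at a 2 s lapse); per-cell ratios of
  condensates to binding events quantify triggering efficiency, compared
  between ligands with the Mann-Whitney U test.
* **Tether geometry.** Maximum intermembrane spacing from a tether design
  (0.34 nm/bp duplex, 0.6 nm/nt single-stranded poly(dT), protein offset
  calibrated to the 14 nm native anchor), and mean relative TIRF intensity
  E[exp(−h/d)] for a fluorophore height distribution in the evanescent
  field.

Because no raw imaging data accompanies the measurements being reproduced,
the package ships a first-class forward simulator (`simulate_*`,
`render_*`): Brownian trajectories with binding-state switching and
single-step photobleaching, pixel-integrated PSF rendering with motion
blur, shot and read noise, evanescent-field attenuation, activation
populations and binding/condensate event streams — all with known ground
truth.

## Worked example

```r
library(synaptrack)

# simulate freely diffusing ligands at D = 2.49 um^2/s, 20 ms frames
opt <- optics_model(exposure = 0.02, frame_interval = 0.02)
gt  <- simulate_trajectories(
  sim_config(box_size = 300, d_free = 2.49, n_frames = 501, rng_seed = 7),
  opt, sub_steps = 1, n_molecules = 120)

# multi-delay step-size distributions and the joint Brownian fit
steps <- build_step_distributions(truth_tracks(gt),
                                  delays = c(0.02, 0.04, 0.06),
                                  frame_interval = 0.02)
fit <- fit_brownian(steps)
fit
#> <diffusion_fit> D = 2.479 um^2/s (95% CI 2.457-2.501), n = 179640 steps (mle)

# photobleach-corrected dwell-time kinetics at a 10 s lapse
rec <- simulate_dwell_records(1000, tau_off = 50, tau_bleach = 300,
                              lapse = 10, rng_seed = 7)
fit_dwell_distribution(rec, lapse = 10, tau_bleach = 300)
#> <dwell_fit> tau_off = 50.7 s (tau_obs 43.4 s, 1000 events, 0 censored)

# maximum intermembrane spacing of a 16 bp duplex + 19 nt poly(dT) tether
max_spacing(tether_design(16, 19))
#> [1] 25.4
```

The diffusion fit recovers the generator's 2.49 µm²/s within its confidence
interval from ~180,000 steps; the dwell fit shows the raw observed decay
(43.4 s) lengthening to the true 50 s once the independently calibrated
bleach rate is removed; and the 36 nt tether design allows ~25 nm of
intermembrane space.

Fitted objects follow broom conventions (`tidy()`, `glance()`) and plot
with `autoplot()`. An end-to-end configurable driver is available as
`run_pipeline()` (YAML or list configs; seeded, hash-stamped outputs).

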