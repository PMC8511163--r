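---
title: "Models and methods behind synaptrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind synaptrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptrack)
```

synaptrack analyses single-molecule TIRF experiments on supported lipid
bilayers (SLBs) presenting synthetic TCR ligands, and ships the forward
simulator used to validate every stage by parameter recovery. This vignette
explains the models, the tunable parameters, the numerical choices, and
what the synthetic data do and do not establish about real data.

## The forward simulator

`simulate_trajectories()` advances each molecule by independent Gaussian
axis displacements with variance $2D\,\Delta t$, with $D$ switching between
a free value (`d_free`, typically 2.4–2.9 µm²/s on a fluid SLB) and a bound
value (`d_bound`, default 0.01 µm²/s: receptor-bound ligands are close to
immobile on the frame timescale). Binding is a two-state Markov process
(`k_on_app`, mean dwell `tau_off_true`); photobleaching is a single
exponential clock that only runs while the field is illuminated and is
absorbing. Boundaries reflect, which preserves surface density without
bookkeeping molecule exchange; the cost is a slight compression of
displacements within one step length of the wall, so density-controlled
simulations meant for diffusion estimation should use fields much larger
than $\sqrt{4 D \Delta t}$ (the test and reproduction scripts use a 300 µm
box, making the boundary layer < 1 % of the area).

Within each exposure the trajectory is sampled at `sub_steps` (default 10)
sub-positions, and `render_movie()` integrates the Gaussian PSF exactly
over each pixel (difference of normal CDFs, not centre sampling) at every
sub-position. This produces the motion blur that the long-exposure
bound-ligand imaging strategy exploits: at a 500 ms exposure, a molecule at
free-ligand diffusivity spreads its photons over a micron-scale trail and
its peak band-pass response falls more than fivefold below that of a
stationary molecule, which is what makes the "bound-only" channel work.
Emission is attenuated by $e^{-h/d}$ for fluorophore height $h$ and
evanescent decay length $d$ (default 100 nm). Camera counts are Poisson in
the expected photons, multiplied by `gain`, plus Gaussian read noise on a
constant baseline. The source measurements do not state camera noise
parameters or photon budgets, so the defaults (5000 photons/s per
fluorophore at the interface, baseline 100 counts, read noise SD 2 counts,
gain 1) were chosen once as representative of a well-exposed EMCCD channel
and are not tuned per analysis; short-exposure acquisitions are simulated
with proportionally higher photon rate, mirroring the higher laser power
used experimentally for fast imaging.

Fluorophore heights for long-tether constructs are drawn from a truncated
Gaussian on $[0, \text{contour length}]$ (`sample_tether_heights()`), a
deliberate stand-in for the worm-like-chain height distribution of a
poly(dT) spacer with 1.5–3 nm persistence length. Only the monotone
ordering of mean height with tether length matters downstream (it drives
the intensity ordering check), so the simpler two-parameter family is used
and documented rather than a full polymer model.

Two generator conventions deserve emphasis:

* **Bleach traces.** `simulate_bleach_traces()` resamples bleach times so
  every emission plateau lasts at least 3 frames and the trace ends at
  background. A particle that bleaches within a frame or two of appearing
  never becomes an analysable trace in a real tracking pipeline, and the
  change-point counter requires two points per segment; the constraint is a
  trace-assembly validity condition, not a change to the study conditions
  (SNR, bleach time and trace counts are untouched).
* **Fraction-bound cells.** `simulate_cell_frames()` assigns bound states
  by stratified allocation: the per-cell bound count is the probabilistic
  rounding of `fraction * n`. At the documented conditions (100 µm²
  footprint, 0.05 µm⁻² density) a cell holds only ~5 ligands, and
  independent Bernoulli draws would add per-cell *truth* noise comparable
  to the tolerance on the recovered median; stratification makes "cells
  with 90 % of ligands bound" true cell by cell, as the condition intends.

## Detection and tracking

`detect_spots()` is a difference-of-Gaussians detector ($\sigma_1 =
d/(2\sqrt2)$ for expected diameter $d$, default 0.4 µm; $\sigma_2 = 1.6
\sigma_1$) with local-maximum selection and intensity-weighted centroid
refinement in a window of the expected diameter. Sub-pixel centroids are
adequate for step-size statistics at these signal levels and are an order
of magnitude cheaper than Gaussian fitting; the refinement is isolated so a
fitter could be dropped in. The default threshold is adaptive (5× the MAD
of the band-pass response), which holds the false-positive rate below
0.1/frame on noise-only images. For long-exposure bound-ligand counting the
threshold must instead be calibrated against brightness:
`calibrate_spot_threshold()` renders a noiseless static spot under the
actual optics and returns a fraction (default one half) of its peak
response, cleanly separating sharp bound spots from blurred free ones.
Detections closer than half a diameter (tied plateau maxima) are merged by
single-linkage clustering, keeping the brightest member.

`link_tracks()` solves frame-to-frame assignment as a linear assignment
problem on the Jaqaman-style augmented cost matrix: candidate links cost
their squared displacement, capped at `max_link_dist` (recommended default
$3\sqrt{4 D \Delta t}$), and every spot may start or end a track at the cap
cost. The Hungarian-method solver (`clue::solve_LSAP`) gives the global
optimum deterministically; a greedy nearest-neighbour linker (ties broken
by distance then index) is kept as a cross-check. Gap closing bridges up to
`max_gap` missed frames at the same radius. Splitting and merging are out
of scope.

## Diffusion estimation

`build_step_distributions()` collects radial displacements at delays that
are integer multiples of the frame interval, using overlapping windows
(maximising data; the common convention). `fit_brownian()` maximises the
joint likelihood of the single-species 2-D Brownian step density across all
delays; the MLE is the closed form $\hat D = \sum r_i^2/(4\tau_i)/N$, which
the tests verify against the analytic derivative. Overlapping windows and
multiple delays correlate observations, so the 95 % CI uses a
cluster-robust (per-track sandwich) standard error with a $t_{G-1}$
quantile when at least 10 tracks contribute; with fewer tracks it falls
back to $D/\sqrt{N_\mathrm{eff}}$ with $N_\mathrm{eff} = \sum_k n_k/k$.
Coverage of this interval is checked empirically over 200 seeded
replicates. An optional static localisation-error term
($E[r^2] = 4D\tau + 4\sigma_\mathrm{loc}^2$) can be co-fitted but is off by
default, since the base model carries no error term. A binned
weighted-least-squares route is provided purely as a cross-check of the
likelihood fit.

## Photobleach step counting

`count_bleach_steps()` segments a trace by recursive binary splitting on
the best mean-shift, accepting a split when the SSE reduction exceeds a
BIC-style penalty $3\hat\sigma^2\log n$, with $\hat\sigma$ the MAD of first
differences divided by $\sqrt2$ (robust to the steps themselves). Only
downward shifts larger than 3 noise SDs count as bleach steps, making the
count invariant under intensity rescaling. Splits keep at least two points
per side, so plateaus shorter than about 3 frames are not resolvable — the
generator constraint above mirrors exactly this. The coincidence
probability $1 - e^{-\rho \pi r^2}$ uses a 0.2 µm default radius; the
diffraction radius behind the published coincidence argument is not stated,
so 0.2 µm (a typical diffraction-limited spot radius at 647 nm) is the
documented choice.

## Dwell times and fraction bound

Visible dwell times are interval-censored: an event seen in $k$ frames
lived between $(k-1)L$ and $kL$ for lapse $L$. The geometric likelihood has
the closed-form MLE $\hat q = A/(A+U)$ (with $A$ the total completed-frame
count and $U$ the number of uncensored events), and
$\hat\tau_\mathrm{obs} = -L/\log\hat q$; this removes the half-frame bias a
naive mean would carry at a 10 s lapse. Right-censoring (movie end, or
track loss as bound receptors are transported to the dense cell centre)
enters the likelihood directly. Because a bleach event is indistinguishable
from unbinding in the image, observed rates add:
$1/\tau_\mathrm{off} = 1/\tau_\mathrm{obs} - 1/\tau_\mathrm{bleach}$. The
bleach time is interpreted on the acquisition clock of the dwell movie —
the natural calibration, since it comes from an immobile control imaged
with the identical lapse/exposure duty cycle; a per-illuminated-second
bleach time can be supplied instead via the `exposure` argument (the two
conventions differ only by the duty-cycle factor, and the package supports
both because the original correction's timebase is unstated). Degenerate
inputs are flagged rather than extrapolated: if
$\tau_\mathrm{obs} \ge \tau_\mathrm{bleach}$ the correction is undefined
and the fit reports a lower bound; if more than half the events are
censored the estimate is likewise flagged as a lower bound, matching how
dwell times measured under tracking loss are reported as "at least".

`estimate_fraction_bound()` counts bound ligands in the long-exposure frame
with the brightness-calibrated threshold, and total ligands in the paired
short-exposure frame. For the denominator the default is calibrated
integrated intensity (footprint counts minus baseline, divided by the
per-molecule flux `photon_rate * exposure * gain`): a free ligand's 50 ms
blur fragments into more than one local maximum in a third of frames, so
raw maxima counting overcounts the denominator and biases the fraction
several points low, whereas total flux is conserved regardless of blur.
Spot counting (with single-linkage merging at the 0.7 µm r.m.s. blur
radius) remains available as `count_mode = "spots"`. The mobility gate
`classify_bound()` uses a 0.5 µm/s rolling-speed threshold at 500 ms
frames: a bound ligand at $D = 0.01$ µm²/s shows apparent speeds around
0.25 ± 0.13 µm/s, so a 0.3 µm/s gate would truncate genuinely bound
segments, while free motion sits near 4 µm/s — 0.5 µm/s keeps bound tracks
intact with an eightfold margin.

## Activation scoring and dose-response

`segment_nucleus_cytosol()` replaces the learned pixel classifier used in
the original analysis with classical operations adequate for synthetic
two-compartment cells: Gaussian smoothing, absolute deviation from the
footprint median (so both bright nuclei in activated cells and dim nuclei
in resting cells are found), a half-maximum threshold (the smoothed edge
ramp crosses half its height on the true boundary) guarded by a noise
floor, morphological cleaning, and a 2-pixel guard band between nucleus and
cytosol. Cells without an interior nucleus, or whose nucleus touches the
footprint edge, are excluded by QC flags. The module boundary lets a
learned segmenter be dropped in for real images. `score_nfat()` computes
the background-subtracted nucleus/cytosol ratio; activation is strictly
ratio > 1, and cells whose cytosol does not clear background are excluded.

`fit_dose_response()` fits the Hill curve by binomial maximum likelihood on
per-density activated counts. The Hill coefficient is bounded to [0.5, 4]
to stabilise fits at realistic cell counts; `max_resp` may be fixed to a
reference ligand's plateau to produce the extrapolated fit used for weak
ligands that never saturate. The EC50 interval is profile likelihood
(1.92-unit drop), and `potency_ratio()` propagates the two profile widths
on the log scale. All-inactive populations return a flagged fit with a
lower-bounded EC50 instead of a number.

## LAT condensates

Condensate regions are found per frame by band-pass filtering and
thresholding with a minimum area, linked with the same LAP linker, and
filtered for persistence (`min_lifetime = 4` frames at a 2 s lapse, the
published counting rule; the boundary is exact — a 3-frame track is
discarded, a 4-frame track counted). `compute_event_ratios()` restricts
both streams to the first 120 s after landing; cells with zero binding
events keep an undefined ratio with a flag since background condensates
occur without binding, which is also why ratios can exceed one.
`compare_groups()` is the two-sided Mann-Whitney U test with tie
correction (via the normal approximation of `wilcox.test`; tests verify it
against exact enumeration of the null for small groups), with stars at
p < 0.01/0.001/0.0001. Colocalization defaults — 0.5 µm radius, 0–10 s
lag — quantify "a condensate forms on top of the event a handful of
seconds later"; the original work does not quantify either window, so the
defaults are documented choices, not sourced values.

## Tether geometry

`max_spacing()` is the fully extended bound: 0.34 nm per duplex base pair,
0.6 nm per single-stranded nucleotide, plus a protein offset calibrated so
the 16 bp duplex-only design gives the 14 nm native receptor–ligand
spacing (offset 8.56 nm). The calibration reproduces the 36 nt and 76 nt
designs at 25.4 and 49.4 nm. How the 14 nm anchor splits between receptor
ectodomain, Fab′ and duplex is not derivable from the main measurements,
so the calibrated-offset convention stands in for the full geometric
derivation. Relative intensity versus height is $E[e^{-h/d}]$ over a
height distribution, strictly decreasing in stochastically larger heights.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` use desk-scale sizes chosen as
the smallest that make each recovery statistically meaningful: 120 tracks
of 500 frames (≈ 60,000 independent steps) for diffusion; 150 traces for
step counting; 1000 events for dwell recovery; 30 cells for fraction-bound
and condensate medians; 200 cells per density for Hill fits; 200 seeded
replicates for CI coverage. Every stochastic stage takes an explicit seed,
`run_pipeline()` stamps outputs with the seed and a config hash, and the
acceptance script derives all sub-seeds from its single `--seed`.

## Limitations

The simulator omits fluorophore blinking and multi-step photophysics
beyond single-step bleaching, 3-D diffusion, membrane microstructure
(gel-phase data are emulated simply by near-zero diffusivity), rebinding,
and force-dependent bond kinetics. Synthetic NFAT cells are two uniform
compartments — passing segmentation tests here demonstrates the scoring
logic, not robustness to real texture, uneven illumination or debris,
which the replaced learned classifier was built for. Condensate material
properties (fusion, intensity scaling) are out of scope. Passing parameter
recovery on these synthetic data shows the estimators are correct under
the stated generative models; it cannot certify detector calibration on a
specific microscope.
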