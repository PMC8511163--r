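Package: synaptrack
Title: Single-Molecule Imaging Analysis of Membrane-Tethered TCR Ligands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for single-molecule TIRF
    experiments on supported lipid bilayers presenting synthetic T cell
    receptor (TCR) ligands. Provides a forward simulator for Brownian
    ligand diffusion, binding-state switching, single-step photobleaching
    and camera physics; spot detection and linear-assignment particle
    linking; diffusion coefficient estimation by simultaneous multi-delay
    step-size distribution fitting; change-point counting of photobleach
    steps; photobleach-corrected censored exponential dwell-time kinetics;
    long/short-exposure fraction-bound estimation under cell footprints;
    NFAT nuclear-translocation scoring with Hill dose-response and EC50
    fitting; LAT condensate detection, persistence filtering and per-cell
    condensate-to-binding-event ratios; and DNA-tether geometry
    calculations for intermembrane spacing and evanescent-field intensity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    clue,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
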