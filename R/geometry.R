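#' DNA tether design
#'
#' Describes a ligand's DNA tether: the hybridised duplex, an optional
#' single-stranded poly(dT) spacer, and the protein contribution (receptor
#' ectodomain plus antibody fragment) to the intermembrane gap.
#'
#' @param duplex_nt Base pairs of double-stranded DNA.
#' @param polyT_nt Nucleotides of single-stranded poly(dT) spacer.
#' @param name Optional label.
#' @param protein_offset Protein contribution to the gap, nm. The default is
#'   calibrated so the 16 nt duplex-only design reproduces the ~14 nm
#'   native receptor:ligand intermembrane spacing
#'   (`14 - 16 * 0.34 = 8.56` nm).
#' @return A `tether_design` object.
#' @examples
#' tether_design(16, 0, "short")
#' @export
tether_design <- function(duplex_nt, polyT_nt = 0, name = NULL,
                          protein_offset = 14 - 16 * 0.34) {
  if (duplex_nt < 0 || polyT_nt < 0) abort("nucleotide counts must be >= 0")
  structure(list(duplex_nt = duplex_nt, polyT_nt = polyT_nt,
                 protein_offset = protein_offset,
                 name = name %||% sprintf("%dnt", duplex_nt + polyT_nt)),
            class = "tether_design")
}

#' @export
print.tether_design <- function(x, ...) {
  cat(sprintf("<tether_design> %s: %d bp duplex + %d nt poly(dT), max spacing %.1f nm\n",
              x$name, x$duplex_nt, x$polyT_nt, max_spacing(x)))
  invisible(x)
}

#' Maximum intermembrane spacing allowed by a tether design
#'
#' Fully extended vertical space between the bilayer and the T cell plasma
#' membrane at a binding event:
#' `duplex_nt * duplex_rise + polyT_nt * ss_contour + protein_offset`.
#' With the default constants (0.34 nm/bp B-form rise, 0.6 nm/nt
#' single-stranded contour) and the calibrated protein offset, the 16, 36
#' and 76 nt designs give 14, 25.4 and 49.4 nm. This is an upper bound
#' ("up to"): a worm-like-chain spacer is almost never fully extended at
#' rest, but can extend under force from the apposing membrane.
#'
#' @param design A [tether_design()].
#' @param duplex_rise Duplex rise per base pair, nm.
#' @param ss_contour Single-stranded contour length per nucleotide, nm.
#' @return Spacing in nanometres.
#' @examples
#' max_spacing(tether_design(16, 0))    # 14 nm anchor
#' max_spacing(tether_design(16, 19))   # ~25 nm
#' max_spacing(tether_design(16, 59))   # ~50 nm
#' @export
max_spacing <- function(design, duplex_rise = 0.34, ss_contour = 0.6) {
  stopifnot(inherits(design, "tether_design"))
  design$duplex_nt * duplex_rise + design$polyT_nt * ss_contour +
    design$protein_offset
}

#' Mean relative TIRF intensity for a fluorophore height distribution
#'
#' The evanescent field decays as `exp(-h / d)`, so a fluorophore population
#' with height distribution `h` has mean relative intensity `E[exp(-h/d)]`
#' (relative to a fluorophore at the interface). Strictly decreasing in
#' height, which is what makes single-particle intensity a height ruler:
#' longer tethers hold the dye higher and render dimmer.
#'
#' @param heights Numeric vector: sampled heights (nm) or a single point
#'   mass.
#' @param evanescent_depth Field decay length, nm.
#' @return Mean relative intensity in (0, 1\].
#' @examples
#' relative_intensity_vs_height(0, 100)    # 1
#' relative_intensity_vs_height(100, 100)  # 1/e
#' @export
relative_intensity_vs_height <- function(heights, evanescent_depth = 100) {
  if (any(heights < 0)) abort("heights must be >= 0")
  .assert_scalar_pos(evanescent_depth, "evanescent_depth")
  mean(exp(-heights / evanescent_depth))
}

#' Sample fluorophore heights for a tether design
#'
#' Truncated-Gaussian stand-in for the worm-like-chain height distribution
#' of a tethered fluorophore: mean at a `extension_fraction` of the
#' single-stranded contour (duplex treated as rigid and membrane-proximal),
#' truncated to `[0, contour]`. Only the monotone mean-height ordering
#' across tether lengths matters downstream.
#'
#' @param design A [tether_design()].
#' @param n Number of samples.
#' @param extension_fraction Mean extension as a fraction of the poly(dT)
#'   contour length.
#' @param sd_fraction Spread as a fraction of contour.
#' @param ss_contour nm per single-stranded nucleotide.
#' @return Numeric vector of heights, nm.
#' @export
sample_tether_heights <- function(design, n, extension_fraction = 0.4,
                                  sd_fraction = 0.25, ss_contour = 0.6) {
  stopifnot(inherits(design, "tether_design"))
  contour <- design$polyT_nt * ss_contour
  if (contour <= 0) return(rep(0, n))
  h <- numeric(0)
  while (length(h) < n) {
    cand <- rnorm(2L * n, extension_fraction * contour, sd_fraction * contour)
    h <- c(h, cand[cand >= 0 & cand <= contour])
  }
  h[seq_len(n)]
}
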