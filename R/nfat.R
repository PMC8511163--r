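#' Render a synthetic NFAT reporter cell image
#'
#' Builds a two-compartment epifluorescence image of one cell: an elliptical
#' footprint containing an interior elliptical nucleus, with the NFAT
#' reporter intensity split between nucleus and cytosol according to
#' `nuc_cyt_ratio` (above-background intensities), plus Gaussian noise. Used
#' to exercise segmentation and activation scoring with known ground truth.
#'
#' @param size_px Image side, pixels.
#' @param footprint_radius_px,nucleus_radius_px Radii in pixels.
#' @param cytosol_intensity Above-background cytosolic mean, counts.
#' @param nuc_cyt_ratio True nucleus/cytosol ratio of background-subtracted
#'   intensities (> 1 renders an activated cell).
#' @param background Background level, counts.
#' @param noise_sd Gaussian noise SD, counts.
#' @param nucleus_offset_px Offset of the nucleus centre from the cell
#'   centre, pixels (x, y).
#' @param rng_seed Seed.
#' @return List: `image` (matrix), `footprint`, `nucleus_mask`,
#'   `cytosol_mask` (logical matrices), `truth` (parameters).
#' @export
render_nfat_cell <- function(size_px = 80, footprint_radius_px = 30,
                             nucleus_radius_px = 12,
                             cytosol_intensity = 300, nuc_cyt_ratio = 2,
                             background = 100, noise_sd = 8,
                             nucleus_offset_px = c(0, 0), rng_seed = 1L) {
  set.seed(as.integer(rng_seed))
  cx <- size_px / 2; cy <- size_px / 2
  xx <- matrix(rep(seq_len(size_px), each = size_px), size_px)   # col index
  yy <- matrix(rep(seq_len(size_px), times = size_px), size_px)  # row index
  fp <- ((xx - cx)^2 + (yy - cy)^2) <= footprint_radius_px^2
  nuc <- ((xx - cx - nucleus_offset_px[1])^2 +
            (yy - cy - nucleus_offset_px[2])^2) <= nucleus_radius_px^2
  nuc <- nuc & fp
  img <- matrix(background, size_px, size_px)
  img[fp] <- background + cytosol_intensity
  img[nuc] <- background + cytosol_intensity * nuc_cyt_ratio
  img <- img + rnorm(length(img), 0, noise_sd)
  cyt <- fp & !nuc
  list(image = img, footprint = fp, nucleus_mask = nuc, cytosol_mask = cyt,
       truth = list(nuc_cyt_ratio = nuc_cyt_ratio, background = background,
                    cytosol_intensity = cytosol_intensity))
}

#' Segment a cell into nucleus and cytosol
#'
#' Classical replacement for learned pixel classification: the image is
#' smoothed, the nucleus is found as the largest interior region whose
#' intensity deviates from the footprint's median (the nucleus is brighter
#' than the cytosol in activated cells and dimmer in resting cells, so the
#' absolute deviation handles both), and the cytosol is the remaining
#' footprint minus a 2-pixel guard band around the nucleus. Cells without a
#' clear interior nucleus, or whose nucleus touches the footprint edge, are
#' excluded via `qc_flag`.
#'
#' @param nfat_image Numeric matrix.
#' @param footprint Logical matrix, the cell footprint.
#' @param smooth_sigma Gaussian smoothing SD, pixels.
#' @param min_area_px Minimum nucleus area.
#' @return List: `nucleus_mask`, `cytosol_mask`, `qc_flag` (`"ok"`,
#'   `"no_nucleus"`, or `"nucleus_touches_edge"`).
#' @export
segment_nucleus_cytosol <- function(nfat_image, footprint,
                                    smooth_sigma = 2, min_area_px = 20) {
  stopifnot(is.matrix(nfat_image), is.matrix(footprint))
  if (!any(footprint)) abort("empty footprint mask")
  sm <- EBImage::gblur(nfat_image, sigma = smooth_sigma)
  med <- median(sm[footprint])
  dev <- abs(sm - med)
  dev[!footprint] <- 0
  devs <- dev[footprint]
  # half-maximum criterion: smoothing turns the compartment edge into a ramp
  # whose midpoint sits on the true boundary; guard with a noise floor
  thr <- max(0.5 * max(devs), median(devs) + 3 * mad(devs))
  cand <- dev > thr & footprint
  cand <- EBImage::opening(cand, EBImage::makeBrush(3, "disc")) > 0
  lab <- EBImage::bwlabel(cand)
  sizes <- tabulate(lab[lab > 0])
  fail <- function(flag) list(nucleus_mask = NULL, cytosol_mask = NULL,
                              qc_flag = flag)
  if (!length(sizes) || max(sizes) < min_area_px) return(fail("no_nucleus"))
  nuc <- lab == which.max(sizes)
  nuc <- EBImage::fillHull(nuc) > 0
  # "clear nucleus" rule: must sit strictly inside the footprint (the
  # half-max boundary pulls in by ~1 px, so test a dilated nucleus)
  edge <- footprint & !(EBImage::erode(footprint,
                                       EBImage::makeBrush(5, "box")) > 0)
  nuc_d <- EBImage::dilate(nuc, EBImage::makeBrush(3, "box")) > 0
  if (any(nuc_d & edge)) return(fail("nucleus_touches_edge"))
  guard <- EBImage::dilate(nuc, EBImage::makeBrush(5, "disc")) > 0
  cyt <- footprint & !guard
  if (!any(cyt)) return(fail("no_nucleus"))
  list(nucleus_mask = nuc, cytosol_mask = cyt, qc_flag = "ok")
}

#' Score NFAT nuclear translocation for one cell
#'
#' A cell counts as activated when the background-subtracted mean nuclear
#' intensity exceeds the background-subtracted mean cytosolic intensity
#' (ratio strictly greater than one). Cells whose cytosolic signal does not
#' rise above background cannot be scored and are flagged.
#'
#' @param nfat_image Numeric matrix.
#' @param nucleus_mask,cytosol_mask Disjoint non-empty logical matrices.
#' @param background Background level, counts (median of a cell-free
#'   region).
#' @return One-row tibble: `nfat_ratio`, `activated`, `qc_flag`.
#' @examples
#' cell <- render_nfat_cell(nuc_cyt_ratio = 2)
#' score_nfat(cell$image, cell$nucleus_mask, cell$cytosol_mask, 100)
#' @export
score_nfat <- function(nfat_image, nucleus_mask, cytosol_mask, background) {
  if (is.null(nucleus_mask) || is.null(cytosol_mask) ||
      !any(nucleus_mask) || !any(cytosol_mask)) {
    abort("nucleus and cytosol masks must be non-empty")
  }
  if (any(nucleus_mask & cytosol_mask)) abort("masks must be disjoint")
  nuc <- mean(nfat_image[nucleus_mask]) - background
  cyt <- mean(nfat_image[cytosol_mask]) - background
  if (cyt <= 0) {
    return(tibble::tibble(nfat_ratio = NA_real_, activated = NA,
                          qc_flag = "cytosol_at_background"))
  }
  ratio <- nuc / cyt
  tibble::tibble(nfat_ratio = ratio, activated = ratio > 1, qc_flag = "ok")
}
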