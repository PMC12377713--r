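# Area-based (Manders-style) puncta colocalization between a reference
# channel (e.g. the tagged protein of interest) and compartment-marker
# channels, including the two-marker mature-lysosome definition
# (LAMP1+ AND CTSD+). Fractions are area ratios of binarized, watershed-
# split puncta masks; punctum-count fractions are emitted as a secondary
# readout.

#' Segment a puncta mask from one channel
#'
#' Fixed processing order: Gaussian denoising (optional) -> rolling-ball
#' background subtraction (optional) -> thresholding -> watershed splitting
#' of touching puncta -> minimum-area filter. Parameters used are attached
#' as attribute `"parameters"`, the retained regions as attribute
#' `"regions"`.
#'
#' @param img A [channel_image()].
#' @param smooth_sigma Gaussian sigma (px) for pre-threshold denoising;
#'   0 disables it. Choose about the PSF width so shot noise does not
#'   speckle the mask edges.
#' @param bg_radius Rolling-ball radius in um, or `NULL` to skip background
#'   subtraction.
#' @param method,threshold Passed to [binarize()].
#' @param min_area_px Minimum punctum area in pixels (default 3, suppressing
#'   single-pixel noise); converted to um^2 via the pixel size.
#' @return A [binary_mask()] of retained puncta.
#' @export
puncta_mask <- function(img, smooth_sigma = 0, bg_radius = NULL,
                        method = "otsu", threshold = NULL, min_area_px = 3) {
  work <- img
  if (smooth_sigma > 0) work <- gaussian_smooth(work, smooth_sigma)
  if (!is.null(bg_radius)) work <- rolling_ball_subtract(work, bg_radius)
  m <- binarize(work, method = method, threshold = threshold)
  thr <- attr(m, "threshold")
  m <- watershed_split(m)
  min_area_um2 <- min_area_px * pixel_size(img)^2
  regions <- connected_components(m, min_area = min_area_um2)
  out <- binary_mask(regions$labels > 0L, pixel_size(img))
  attr(out, "regions") <- regions
  attr(out, "parameters") <- list(bg_radius = bg_radius, method = method,
                                  threshold = thr, min_area_px = min_area_px)
  out
}

#' Overlap fractions between two puncta masks
#'
#' The overlap is the pixelwise AND. `fraction_of_A` is overlap area over
#' reference-mask area (the fraction of reference puncta area residing in
#' the marker compartment); `fraction_of_B` the converse. Fractions with an
#' empty denominator are `NA` (undefined, never 0).
#'
#' @param ref Reference-channel [binary_mask()].
#' @param marker Marker-channel [binary_mask()] of the same shape.
#' @param cell_id,compartment Optional identifiers carried into the result.
#' @return A one-row `data.frame`: areas (um^2) of reference, marker and
#'   overlap, both fractions, and punctum-count overlap fractions
#'   (`count_fraction_of_A`/`_B`: puncta with any overlapping pixel).
#' @export
coloc_fraction <- function(ref, marker, cell_id = NA, compartment = NA) {
  ov <- mask_and(ref, marker)   # validates shapes
  a_px <- sum(ref); b_px <- sum(marker); o_px <- sum(ov)
  ps <- pixel_size(ref)
  cc_ref <- connected_components(ref)
  cc_mark <- connected_components(marker)
  count_frac <- function(cc, other) {
    if (!nrow(cc$regions)) return(NA_real_)
    hit <- vapply(cc$regions$label, function(l)
      any(other[cc$labels == l]), logical(1))
    mean(hit)
  }
  data.frame(cell_id = cell_id, compartment = compartment,
             area_A_um2 = a_px * ps^2, area_B_um2 = b_px * ps^2,
             area_overlap_um2 = o_px * ps^2,
             fraction_of_A = if (a_px > 0) o_px / a_px else NA_real_,
             fraction_of_B = if (b_px > 0) o_px / b_px else NA_real_,
             count_fraction_of_A = count_frac(cc_ref, unclass(marker)),
             count_fraction_of_B = count_frac(cc_mark, unclass(ref)),
             stringsAsFactors = FALSE)
}

#' Mature-lysosome mask from two markers
#'
#' Mature lysosomes are defined by joint positivity for both markers
#' (LAMP1+ CTSD+); this is the pixelwise AND of the two marker masks.
#'
#' @param lamp1,ctsd [binary_mask()]s of identical shape.
#' @return A [binary_mask()].
#' @export
mature_lysosome_mask <- function(lamp1, ctsd) mask_and(lamp1, ctsd)

#' Per-cell and pooled colocalization report
#'
#' Each cell supplies a reference mask and one or more named marker masks
#' (already segmented, e.g. by [puncta_mask()]). Cells whose reference mask
#' is empty yield undefined fractions; they are flagged, reported via
#' `message()`, and excluded from the pooled means.
#'
#' @param cells List of cells; each a list with elements `ref` (a
#'   [binary_mask()]) and `markers` (named list of [binary_mask()]s).
#'   Optionally `id`.
#' @return List with `per_cell` (one row per cell x compartment) and
#'   `summary` (per compartment: n cells used, mean and s.e.m. of
#'   `fraction_of_A` and `fraction_of_B`).
#' @export
compartment_report <- function(cells) {
  rows <- list()
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    id <- cell$id %||% i
    for (comp in names(cell$markers)) {
      r <- coloc_fraction(cell$ref, cell$markers[[comp]],
                          cell_id = id, compartment = comp)
      r$excluded <- is.na(r$fraction_of_A)
      if (r$excluded)
        message(sprintf("cell %s / %s: empty reference mask; excluded from mean",
                        id, comp))
      rows[[length(rows) + 1L]] <- r
    }
  }
  per_cell <- do.call(rbind, rows)
  sem <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0
  by_comp <- split(per_cell, per_cell$compartment)
  summ <- do.call(rbind, lapply(names(by_comp),
    function(comp) {
      d <- by_comp[[comp]]
      d <- d[!d$excluded, , drop = FALSE]
      data.frame(compartment = comp,
                 n_cells = nrow(d),
                 mean_fraction_of_A = mean(d$fraction_of_A),
                 sem_fraction_of_A = sem(d$fraction_of_A),
                 mean_fraction_of_B = mean(d$fraction_of_B, na.rm = TRUE),
                 sem_fraction_of_B = sem(d$fraction_of_B[!is.na(d$fraction_of_B)]),
                 stringsAsFactors = FALSE)
    }))
  rownames(summ) <- NULL
  list(per_cell = per_cell, summary = summ)
}
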