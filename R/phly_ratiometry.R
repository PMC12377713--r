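# Ratiometric endolysosomal pH quantification for LAMP1-targeted dual-
# fluorophore sensors (FIRE-pHly): the green fluorophore (mTFP1) is
# pH-sensitive, the red (mCherry) is a pH-stable reference, so a higher
# green/red (G/R) ratio within a punctum indicates a less acidic lumen.
# The per-cell workflow: cell-body masking on the green channel, per-channel
# preprocessing, bright-spot detection on the red channel within the body,
# per-punctum G/R ratios, per-cell summaries, puncta-count study weights,
# and Welch / Mann-Whitney group comparisons with cells as units.

#' Segment the cell body from the green channel
#'
#' Gaussian smoothing (sigma, in px) -> rolling-ball background subtraction
#' (radius, um) -> thresholding; the largest connected component is retained
#' as the cell body.
#'
#' @param green Green-channel [channel_image()].
#' @param sigma Gaussian sigma in pixels (default 8).
#' @param bg_radius Rolling-ball radius in um (default 18).
#' @param method,threshold Passed to [binarize()] (default Otsu).
#' @return A [binary_mask()] of the cell body.
#' @export
cell_body_mask <- function(green, sigma = 8, bg_radius = 18,
                           method = "otsu", threshold = NULL) {
  sm <- gaussian_smooth(green, sigma)
  sm <- rolling_ball_subtract(sm, bg_radius)
  m <- tryCatch(binarize(sm, method = method, threshold = threshold),
                error = function(e) stop("no cell detected: ",
                                         conditionMessage(e)))
  cc <- connected_components(m)
  if (!nrow(cc$regions)) stop("no cell detected")
  biggest <- cc$regions$label[which.max(cc$regions$area_px)]
  binary_mask(cc$labels == biggest, pixel_size(green))
}

#' Preprocess a sensor channel before punctum measurement
#'
#' Low-pass filter (cutoff in px) followed by rolling-ball background
#' subtraction (radius in um). The order matters: smoothing first keeps the
#' background estimate from chasing single-pixel noise.
#'
#' @param img A [channel_image()].
#' @param lp_cutoff Low-pass cutoff in pixels (default 4).
#' @param bg_radius Rolling-ball radius in um (default 1.2).
#' @return Preprocessed [channel_image()].
#' @export
preprocess_channel <- function(img, lp_cutoff = 4, bg_radius = 1.2) {
  rolling_ball_subtract(low_pass(img, lp_cutoff), bg_radius)
}

log_kernel <- function(sigma) {
  r <- max(2L, ceiling(3 * sigma) + 1L)
  g <- outer(-r:r, -r:r, function(x, y) {
    s2 <- sigma^2
    rho2 <- x^2 + y^2
    (rho2 - 2 * s2) / s2^2 * exp(-rho2 / (2 * s2))
  })
  k <- -g * sigma^2            # scale-normalized, positive at blob centers
  k - mean(k)                  # zero response on constant background
}

#' Detect bright puncta at a fixed physical diameter
#'
#' Scale-selective blob detection: the channel is convolved with a
#' scale-normalized Laplacian-of-Gaussian kernel at
#' `sigma = diameter_px / (2 * sqrt(2))` (the standard blob-scale relation);
#' local maxima of the response inside the cell body, with channel intensity
#' at the peak at or above `intensity_threshold`, become detections. Peaks
#' closer than one diameter are suppressed in favour of the stronger
#' response. Each detection is realized as a disk of the stated diameter,
#' clipped to the image and with contested pixels assigned to the nearest
#' center.
#'
#' @param red Preprocessed red-channel [channel_image()].
#' @param body Cell-body [binary_mask()].
#' @param diameter Spot diameter in micrometres (default 1.5).
#' @param intensity_threshold Minimum channel intensity at the peak
#'   (default 0; in practice adjusted per image).
#' @param min_response_frac Peaks whose blob response is below this fraction
#'   of the image's maximum response are discarded (default 0.05); this
#'   rejects numerically flat ripple on empty background while keeping any
#'   spot within 20x of the brightest.
#' @return A [labeled_regions()] of detected puncta (attribute `"centers"`
#'   holds the 0-based peak coordinates).
#' @export
detect_puncta <- function(red, body, diameter = 1.5,
                          intensity_threshold = 0,
                          min_response_frac = 0.05) {
  if (!is.numeric(diameter) || length(diameter) != 1L || diameter <= 0)
    stop("diameter must be a single positive number (um)")
  ps <- pixel_size(red)
  d_px <- diameter / ps
  sigma <- d_px / (2 * sqrt(2))
  k <- log_kernel(sigma)
  r <- (nrow(k) - 1L) / 2L
  p <- pad_reflect(unclass(red), r)
  resp <- EBImage::filter2(p, k, boundary = "circular")
  resp <- resp[(r + 1L):(r + nrow(red)), (r + 1L):(r + ncol(red)),
               drop = FALSE]
  # local maxima over the 8-neighborhood, above the relative response floor
  is_max <- resp > max(resp) * min_response_frac & resp > 0
  for (s in list(c(1L,0L), c(-1L,0L), c(0L,1L), c(0L,-1L),
                 c(1L,1L), c(1L,-1L), c(-1L,1L), c(-1L,-1L)))
    is_max <- is_max & resp >= shift_mat(resp, s[1L], s[2L], fill = -Inf)
  is_max <- is_max & unclass(body) & unclass(red) >= intensity_threshold
  idx <- which(is_max)
  lab <- matrix(0L, nrow(red), ncol(red))
  centers <- cbind(row = numeric(0), col = numeric(0))
  if (length(idx)) {
    rows <- (idx - 1L) %% nrow(red) + 1L
    cols <- (idx - 1L) %/% nrow(red) + 1L
    ord <- order(-resp[idx], rows, cols)     # deterministic
    rows <- rows[ord]; cols <- cols[ord]
    keep <- logical(length(rows))
    for (i in seq_along(rows)) {
      if (!any(keep)) { keep[i] <- TRUE; next }
      dd <- (rows[keep] - rows[i])^2 + (cols[keep] - cols[i])^2
      if (all(dd >= d_px^2)) keep[i] <- TRUE
    }
    rows <- rows[keep]; cols <- cols[keep]
    # paint disks, contested pixels to the nearest center
    rad <- d_px / 2
    best_d2 <- matrix(Inf, nrow(red), ncol(red))
    for (i in seq_along(rows)) {
      rr <- max(1L, floor(rows[i] - rad)):min(nrow(red), ceiling(rows[i] + rad))
      cc <- max(1L, floor(cols[i] - rad)):min(ncol(red), ceiling(cols[i] + rad))
      d2 <- outer((rr - rows[i])^2, (cc - cols[i])^2, `+`)
      sel <- d2 <= rad^2 & d2 < best_d2[rr, cc]
      block_lab <- lab[rr, cc]; block_d2 <- best_d2[rr, cc]
      block_lab[sel] <- i; block_d2[sel] <- d2[sel]
      lab[rr, cc] <- block_lab; best_d2[rr, cc] <- block_d2
    }
    centers <- cbind(row = rows - 1, col = cols - 1)  # 0-based
  }
  out <- structure(list(labels = lab, regions = region_table(lab, ps),
                        pixel_size_um = ps),
                   class = "labeled_regions")
  attr(out, "centers") <- centers
  out
}

#' Measure per-punctum mean intensities and G/R ratios
#'
#' For each region, the mean green and mean red intensity over its pixels
#' and their ratio. Regions with zero mean red (segmentation artifacts) are
#' flagged invalid, reported via `message()`, and excluded.
#'
#' @param green,red Aligned [channel_image()]s.
#' @param regions A [labeled_regions()] (e.g. from [detect_puncta()]).
#' @param cell_id Optional identifier carried into the result.
#' @return `data.frame`: `cell_id`, `punctum_id`, `area_um2`, `mean_green`,
#'   `mean_red`, `gr_ratio`; invalid puncta dropped.
#' @export
measure_puncta <- function(green, red, regions, cell_id = NA) {
  if (!all(dim(green) == dim(red)) ||
      !all(dim(green) == dim(regions$labels)))
    stop("green, red and regions must share one shape")
  res <- regions$regions
  if (!nrow(res))
    return(data.frame(cell_id = character(0), punctum_id = integer(0),
                      area_um2 = numeric(0), mean_green = numeric(0),
                      mean_red = numeric(0), gr_ratio = numeric(0)))
  lab <- regions$labels
  f <- factor(lab[lab > 0L], levels = res$label)
  mg <- as.numeric(tapply(unclass(green)[lab > 0L], f, mean))
  mr <- as.numeric(tapply(unclass(red)[lab > 0L], f, mean))
  out <- data.frame(cell_id = cell_id, punctum_id = res$label,
                    area_um2 = res$area_um2,
                    mean_green = mg, mean_red = mr,
                    gr_ratio = mg / mr, stringsAsFactors = FALSE)
  bad <- out$mean_red == 0
  if (any(bad)) {
    message(sprintf("%d punctum/a with zero red signal excluded (cell %s)",
                    sum(bad), cell_id))
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Summarize one cell's punctum measurements
#'
#' @param measurements Output of [measure_puncta()] for one cell.
#' @param body_area_um2 Cell-body area in um^2.
#' @param cell_id,group Identifiers.
#' @return One-row `data.frame`: `n_puncta`, `density_per_100um2`
#'   (= n / area x 100), unweighted `mean_gr` and `mean_area_um2` (NA when
#'   the cell has no valid puncta).
#' @export
summarize_cell <- function(measurements, body_area_um2, cell_id = NA,
                           group = NA) {
  n <- nrow(measurements)
  data.frame(cell_id = cell_id, group = group,
             cell_body_area_um2 = body_area_um2,
             n_puncta = n,
             density_per_100um2 = n / body_area_um2 * 100,
             mean_gr = if (n) mean(measurements$gr_ratio) else NA_real_,
             mean_area_um2 = if (n) mean(measurements$area_um2) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Quantify one cell end to end
#'
#' [cell_body_mask()] on the green channel, [preprocess_channel()] on both
#' channels, [detect_puncta()] on the red channel inside the body,
#' [measure_puncta()] and [summarize_cell()].
#'
#' @param green,red Raw [channel_image()]s.
#' @param cell_id,group Identifiers.
#' @param spot_diameter Spot diameter in um (default 1.5).
#' @param intensity_threshold Per-image spot intensity threshold.
#' @param body_sigma,body_bg_radius,lp_cutoff,punct_bg_radius Preprocessing
#'   parameters (pixels / um), see the stage functions.
#' @param body_threshold Optional fixed cell-body threshold.
#' @return List with `summary` (one-row data.frame), `measurements`,
#'   `body` mask.
#' @export
quantify_phly_cell <- function(green, red, cell_id = NA, group = NA,
                               spot_diameter = 1.5, intensity_threshold = 0,
                               body_sigma = 8, body_bg_radius = 18,
                               lp_cutoff = 4, punct_bg_radius = 1.2,
                               body_threshold = NULL) {
  body <- cell_body_mask(green, sigma = body_sigma,
                         bg_radius = body_bg_radius,
                         threshold = body_threshold)
  g <- preprocess_channel(green, lp_cutoff, punct_bg_radius)
  r <- preprocess_channel(red, lp_cutoff, punct_bg_radius)
  regions <- detect_puncta(r, body, diameter = spot_diameter,
                           intensity_threshold = intensity_threshold)
  meas <- measure_puncta(g, r, regions, cell_id = cell_id)
  summ <- summarize_cell(meas, mask_area_um2(body), cell_id = cell_id,
                         group = group)
  list(summary = summ, measurements = meas, body = body)
}

#' Attach puncta-count study weights to cell summaries
#'
#' Each cell's weight is its share of all puncta in the study rescaled to a
#' fixed total: `w_i = (n_i / N_total) * total`, with `total = 10` so the
#' weights sum to 10 across the study.
#'
#' @param cells `data.frame` of cell summaries with an `n_puncta` column.
#' @param total Weight total (default 10).
#' @return `cells` with a `weight` column.
#' @export
assign_weights <- function(cells, total = 10) {
  n_total <- sum(cells$n_puncta)
  if (n_total <= 0) stop("no puncta in the study: weights undefined")
  cells$weight <- cells$n_puncta / n_total * total
  cells
}

#' Weighted per-group mean of a cell-level field
#'
#' Per group: the weighted mean `sum(w_i x_i) / sum(w_i)` over that group's
#' cells, plus a weighted dispersion; per-cell weighted values
#' (`w_i * x_i`) are also emitted for the weighted variant of the
#' downstream test.
#'
#' @param cells Cell summaries with weights ([assign_weights()]).
#' @param field Column to summarize (e.g. `"mean_gr"`, `"mean_area_um2"`).
#' @return List with `summary` (per group: n, weighted mean, weighted sd)
#'   and `per_cell` (cells with a `weighted_value` column).
#' @export
weighted_group_stat <- function(cells, field) {
  if (!field %in% names(cells)) stop("unknown field: ", field)
  if (is.null(cells$weight)) stop("assign_weights() first")
  groups <- split(cells, cells$group)
  if (any(vapply(groups, nrow, integer(1)) == 0L)) stop("empty group")
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    d <- groups[[g]]
    ok <- !is.na(d[[field]])
    d <- d[ok, , drop = FALSE]
    if (!nrow(d)) stop("empty group after removing missing values: ", g)
    wm <- weighted.mean(d[[field]], d$weight)
    wvar <- sum(d$weight * (d[[field]] - wm)^2) / sum(d$weight)
    data.frame(group = g, n_cells = nrow(d), weighted_mean = wm,
               weighted_sd = sqrt(wvar), stringsAsFactors = FALSE)
  }))
  cells$weighted_value <- cells$weight * cells[[field]]
  list(summary = summ, per_cell = cells)
}

#' Compare two groups of cells (Welch t or Mann-Whitney)
#'
#' Cells are the units of analysis. `test = "welch"` runs the unpaired
#' two-tailed t-test without the equal-variance assumption
#' (Welch-Satterthwaite degrees of freedom); `test = "mannwhitney"` the
#' two-tailed Mann-Whitney U test (exact for small samples without ties,
#' tie-corrected normal approximation otherwise). By default the raw
#' per-cell values are compared; `weighted = TRUE` compares the
#' weight-multiplied per-cell values `w_i * x_i` instead.
#'
#' @param cells Cell summaries with a `group` column (two levels).
#' @param field Column to compare.
#' @param test `"welch"` or `"mannwhitney"`.
#' @param weighted Compare `w_i * x_i` instead of `x_i`.
#' @return One-row `data.frame`: group means, test statistic (`t` or `U`),
#'   degrees of freedom (Welch only), two-tailed `p_value`, `test` name.
#' @export
compare_groups <- function(cells, field, test = c("welch", "mannwhitney"),
                           weighted = FALSE) {
  test <- match.arg(test)
  if (!field %in% names(cells)) stop("unknown field: ", field)
  g <- unique(cells$group)
  if (length(g) != 2L)
    stop("exactly two groups required, got: ", paste(g, collapse = ", "))
  val <- if (weighted) {
    if (is.null(cells$weight)) stop("assign_weights() first")
    cells$weight * cells[[field]]
  } else cells[[field]]
  x <- val[cells$group == g[1L] & !is.na(val)]
  y <- val[cells$group == g[2L] & !is.na(val)]
  if (test == "welch") {
    if (length(x) < 2L || length(y) < 2L)
      stop("welch test requires n >= 2 per group")
    if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
      ht <- list(statistic = c(t = 0), parameter = c(df = NA_real_),
                 p.value = 1)
    } else ht <- t.test(x, y, var.equal = FALSE)
    data.frame(group_1 = g[1L], group_2 = g[2L],
               mean_1 = mean(x), mean_2 = mean(y),
               statistic = unname(ht$statistic),
               df = unname(ht$parameter),
               p_value = ht$p.value, test = "welch",
               stringsAsFactors = FALSE)
  } else {
    if (!length(x) || !length(y))
      stop("mann-whitney requires n >= 1 per group")
    ht <- suppressWarnings(wilcox.test(x, y))
    data.frame(group_1 = g[1L], group_2 = g[2L],
               mean_1 = mean(x), mean_2 = mean(y),
               statistic = unname(ht$statistic),
               df = NA_real_,
               p_value = ht$p.value, test = "mannwhitney",
               stringsAsFactors = FALSE)
  }
}
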