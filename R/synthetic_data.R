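# Seeded synthetic-data generators with exact ground truth for every
# pipeline stage. Identical seed and parameters give bit-identical outputs;
# generators never emit NaN, negative intensities or negative counts.

with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

#' Simulate a dual-tag spectral-count table with planted interactors
#'
#' Emulates the 2 tags x bait/control x 2 replicates IP design. Molecular
#' weights are uniform over `mw_range_kda`; control TSCs are Poisson with
#' mean proportional to MW (`mean_control_tsc * MW / 50`, so a 50 kDa
#' protein averages `mean_control_tsc` counts); background proteins draw
#' bait counts from the same mean, planted interactors from
#' `enrichment_factor` times it. Dropout zeroes any single TSC with
#' probability `dropout_prob`.
#'
#' @param n_background,n_interactors Numbers of background and planted
#'   interactor proteins.
#' @param enrichment_factor Bait/control mean ratio for interactors (>= 1).
#' @param mean_control_tsc Mean control TSC at 50 kDa.
#' @param mw_range_kda Molecular-weight range (kDa).
#' @param dropout_prob Per-cell zeroing probability.
#' @param seed Integer seed.
#' @param tags Tag labels.
#' @return List with `table` (a [spectral_count_table()]) and `truth`
#'   (data.frame: accession, `is_interactor`).
#' @export
sim_spectral_counts <- function(n_background = 500, n_interactors = 20,
                                enrichment_factor = 10,
                                mean_control_tsc = 20,
                                mw_range_kda = c(20, 150),
                                dropout_prob = 0, seed = 1,
                                tags = c("tagA", "tagB")) {
  if (n_background < 0 || n_interactors < 0) stop("n must be >= 0")
  if (enrichment_factor < 1) stop("enrichment_factor must be >= 1")
  if (dropout_prob < 0 || dropout_prob > 1) stop("dropout_prob in [0,1]")
  n <- n_background + n_interactors
  design <- default_design(tags)
  with_seed(seed, {
    mw <- runif(n, mw_range_kda[1L], mw_range_kda[2L])
    is_int <- c(rep(TRUE, n_interactors), rep(FALSE, n_background))
    base_mean <- mean_control_tsc * mw / 50
    counts <- matrix(0, n, nrow(design),
                     dimnames = list(NULL, design$sample))
    for (j in seq_len(nrow(design))) {
      mu <- if (design$role[j] == "bait")
        ifelse(is_int, enrichment_factor * base_mean, base_mean)
      else base_mean
      counts[, j] <- rpois(n, mu)
    }
    if (dropout_prob > 0) {
      drop <- matrix(runif(length(counts)) < dropout_prob, n)
      counts[drop] <- 0
    }
    acc <- sprintf("SIM%05d", seq_len(n))
    sym <- c(sprintf("INT%d", seq_len(n_interactors)),
             sprintf("BG%d", seq_len(n_background)))[seq_len(n)]
    list(table = spectral_count_table(acc, sym, mw, counts, design),
         truth = data.frame(accession = acc, is_interactor = is_int,
                            stringsAsFactors = FALSE))
  })
}

# place k disk centers with pairwise min distance, uniform in the margin box
place_centers <- function(k, shape, margin, min_dist, max_tries = 20000L) {
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centers) < k) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("puncta cannot fit in the image without overlap; enlarge the ",
           "image or reduce n/radius")
    cand <- c(runif(1, margin, shape[1L] - margin),
              runif(1, margin, shape[2L] - margin))
    if (!nrow(centers) ||
        all((centers[, 1L] - cand[1L])^2 +
              (centers[, 2L] - cand[2L])^2 >= min_dist^2))
      centers <- rbind(centers, cand)
  }
  centers
}

disk_mask <- function(shape, centers, radius_px) {
  m <- matrix(FALSE, shape[1L], shape[2L])
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1L]; c0 <- centers[i, 2L]
    rr <- max(1L, floor(r0 - radius_px)):min(shape[1L], ceiling(r0 + radius_px))
    cc <- max(1L, floor(c0 - radius_px)):min(shape[2L], ceiling(c0 + radius_px))
    d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
    m[rr, cc] <- m[rr, cc] | d2 <= radius_px^2
  }
  m
}

#' Simulate a two-channel puncta pair with a known overlap fraction
#'
#' Reference puncta are placed uniformly without touching; a fraction of
#' marker puncta is co-centered with reference puncta (exact overlap by
#' construction) and the rest placed disjointly, so the true area overlap
#' fraction of the reference mask is `round(target * n_ref) / n_ref` for
#' equal-radius disks. Images are the masks at `amplitude`, blurred by a
#' Gaussian PSF and corrupted with additive Gaussian noise (clipped at 0).
#' Ground-truth masks are returned pre-blur.
#'
#' @param shape_px Image shape (rows, cols).
#' @param pixel_size_um Pixel size (um).
#' @param n_ref,n_marker Numbers of reference and marker puncta.
#' @param target_overlap_fraction Target fraction of reference area
#'   overlapped, in `[0, 1]`.
#' @param punctum_radius_um Punctum radius (um).
#' @param psf_sigma_px PSF sigma (px).
#' @param noise_sd Additive noise standard deviation (intensity units).
#' @param amplitude Punctum peak intensity before blur.
#' @param seed Integer seed.
#' @return List with channel images `ref_img`/`marker_img`, truth masks
#'   `ref_mask`/`marker_mask`, and `true_fraction` (exact, from the masks).
#' @export
sim_coloc_images <- function(shape_px = c(256, 256), pixel_size_um = 0.1,
                             n_ref = 12, n_marker = 12,
                             target_overlap_fraction = 0.5,
                             punctum_radius_um = 0.4, psf_sigma_px = 1,
                             noise_sd = 0, amplitude = 100, seed = 1) {
  if (target_overlap_fraction < 0 || target_overlap_fraction > 1)
    stop("target_overlap_fraction must be in [0, 1]")
  r_px <- punctum_radius_um / pixel_size_um
  k <- round(target_overlap_fraction * n_ref)
  k <- min(k, n_marker)
  with_seed(seed, {
    n_free <- n_marker - k
    margin <- r_px + 3
    min_dist <- 2 * r_px + 4
    all_centers <- place_centers(n_ref + n_free, shape_px, margin, min_dist)
    ref_centers <- all_centers[seq_len(n_ref), , drop = FALSE]
    marker_centers <- rbind(ref_centers[seq_len(k), , drop = FALSE],
                            all_centers[n_ref + seq_len(n_free), ,
                                        drop = FALSE])
    ref_mask <- disk_mask(shape_px, ref_centers, r_px)
    marker_mask <- disk_mask(shape_px, marker_centers, r_px)
    true_fraction <- if (sum(ref_mask) > 0)
      sum(ref_mask & marker_mask) / sum(ref_mask) else NA_real_
    render <- function(mask, name) {
      img <- channel_image(mask * amplitude, pixel_size_um, name)
      if (psf_sigma_px > 0) img <- gaussian_smooth(img, psf_sigma_px)
      if (noise_sd > 0) {
        v <- unclass(img) + rnorm(length(img), 0, noise_sd)
        v[v < 0] <- 0
        img <- channel_image(v, pixel_size_um, name)
      }
      img
    }
    list(ref_img = render(ref_mask, "ref"),
         marker_img = render(marker_mask, "marker"),
         ref_mask = binary_mask(ref_mask, pixel_size_um),
         marker_mask = binary_mask(marker_mask, pixel_size_um),
         true_fraction = true_fraction)
  })
}

#' Simulate a two-group ratiometric pH imaging cohort
#'
#' Per cell: a bright body disk in the green channel (diffuse sensor
#' background), red puncta of constant intensity, and green punctum signal
#' equal to the cell's true G/R ratio times the red signal. Cell ratios are
#' drawn per group from a normal distribution (`true_gr_mean[group]`,
#' `between_cell_sd`), truncated at 0.05. With `images = FALSE` only the
#' ground-truth cell table is generated (for statistical replicates where
#' image rendering adds nothing).
#'
#' @param n_cells_per_group Named integer vector, cells per group
#'   (e.g. `c(WT = 10, MUT = 13)`).
#' @param true_gr_mean Named numeric vector of group mean G/R ratios.
#' @param between_cell_sd Between-cell SD of the true ratio.
#' @param puncta_per_cell_range Integer range of puncta per cell.
#' @param punctum_radius_um,body_radius_um Geometry (um).
#' @param pixel_size_um Pixel size (um).
#' @param noise_sd Additive intensity noise SD.
#' @param red_amplitude,body_level Intensities of red puncta and green body.
#' @param seed Integer seed.
#' @param images Render images (`TRUE`) or return only the truth table.
#' @return List with `truth` (cell_id, group, true_gr, n_puncta) and, when
#'   `images = TRUE`, `cells`: per cell a list of `green`/`red`
#'   [channel_image()]s.
#' @export
sim_phly_cohort <- function(n_cells_per_group = c(WT = 10, MUT = 13),
                            true_gr_mean = c(WT = 0.8, MUT = 1.1),
                            between_cell_sd = 0.1,
                            puncta_per_cell_range = c(6, 14),
                            punctum_radius_um = 0.6, body_radius_um = 10,
                            pixel_size_um = 0.2, noise_sd = 0,
                            red_amplitude = 100, body_level = 40,
                            seed = 1, images = TRUE) {
  if (any(true_gr_mean <= 0)) stop("true_gr_mean must be > 0")
  if (body_radius_um <= 3 * punctum_radius_um)
    stop("body radius too small for the punctum geometry")
  groups <- names(n_cells_per_group)
  if (is.null(groups) || !all(groups %in% names(true_gr_mean)))
    stop("n_cells_per_group and true_gr_mean must share group names")
  with_seed(seed, {
    truth <- do.call(rbind, lapply(groups, function(g) {
      n <- n_cells_per_group[[g]]
      data.frame(cell_id = sprintf("%s_%02d", g, seq_len(n)), group = g,
                 true_gr = pmax(0.05, rnorm(n, true_gr_mean[[g]],
                                            between_cell_sd)),
                 n_puncta = {
                   rng <- seq(puncta_per_cell_range[1L],
                              puncta_per_cell_range[2L])
                   rng[sample.int(length(rng), n, replace = TRUE)]
                 },
                 stringsAsFactors = FALSE)
    }))
    rownames(truth) <- NULL
    if (!images) return(list(truth = truth, cells = NULL))
    r_px <- punctum_radius_um / pixel_size_um
    body_r_px <- body_radius_um / pixel_size_um
    pad <- ceiling(2 / pixel_size_um)       # room for the background ball
    side <- ceiling(2 * (body_r_px + pad)) + 1L
    ctr <- (side + 1) / 2
    cells <- lapply(seq_len(nrow(truth)), function(i) {
      shape <- c(side, side)
      body <- disk_mask(shape, cbind(ctr, ctr), body_r_px)
      # puncta well inside the body (clear of the edge by the punctum
      # radius plus the background ball) so background estimation is exact
      ball_px <- ceiling(1.2 / pixel_size_um)
      max_off <- body_r_px - (r_px + ball_px + 4)
      if (max_off <= 2 * r_px) stop("body radius too small for the punctum geometry")
      cen <- place_centers(truth$n_puncta[i], shape,
                           margin = ctr - max_off / sqrt(2),
                           min_dist = max(2 * r_px + 6, 2.2 / pixel_size_um))
      red <- matrix(0, side, side)
      pm <- disk_mask(shape, cen, r_px)
      red[pm] <- red_amplitude
      green <- body * body_level + truth$true_gr[i] * red
      addnoise <- function(m) {
        if (noise_sd > 0) m <- m + rnorm(length(m), 0, noise_sd)
        m[m < 0] <- 0
        m
      }
      list(green = channel_image(addnoise(green), pixel_size_um, "green"),
           red = channel_image(addnoise(red), pixel_size_um, "red"))
    })
    names(cells) <- truth$cell_id
    list(truth = truth, cells = cells)
  })
}

#' Simulate a blot-densitometry table
#'
#' Log-normal band intensities with group means `wt_mean` / `mut_mean` and
#' coefficient of variation `cv` (`cv = 0` gives exact constants); V0a1 IP
#' and input bands fluctuate around 1 with the same cv.
#'
#' @param n_per_group Samples per genotype.
#' @param wt_mean,mut_mean Group mean V1 band intensities (> 0).
#' @param cv Coefficient of variation (>= 0).
#' @param seed Integer seed.
#' @return List with `table` (a blot measurement data.frame) and
#'   `true_reduction_pct` = `(1 - mut_mean / wt_mean) * 100`.
#' @export
sim_blot_table <- function(n_per_group = 5, wt_mean = 1, mut_mean = 0.6828,
                           cv = 0.1, seed = 1) {
  if (wt_mean <= 0 || mut_mean <= 0) stop("means must be > 0")
  if (cv < 0) stop("cv must be >= 0")
  rln <- function(n, mean) {
    if (cv == 0) return(rep(mean, n))
    sdlog <- sqrt(log(1 + cv^2))
    rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
  }
  with_seed(seed, {
    n <- n_per_group
    tab <- data.frame(
      sample = sprintf("S%02d", seq_len(2L * n)),
      genotype = rep(c("WT", "MUT"), each = n),
      v1_band = c(rln(n, wt_mean), rln(n, mut_mean)),
      v0a1_ip_band = rln(2L * n, 1),
      v0a1_input_band = rln(2L * n, 1),
      stringsAsFactors = FALSE)
    list(table = tab,
         true_reduction_pct = (1 - mut_mean / wt_mean) * 100)
  })
}
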