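# Western-blot densitometry for V-ATPase assembly co-IP assays: V1-subunit
# band intensities after V0a1 pulldown, normalized to the wild-type V0a1 IP
# signal (interaction) or to the per-sample V0a1 input (total protein), and
# the percent reduction of the mutant group relative to wild type.
# Band quantification itself (gel image -> intensity) is out of scope;
# inputs are intensity tables.

check_blot_table <- function(measurements) {
  need <- c("sample", "genotype", "v1_band", "v0a1_ip_band",
            "v0a1_input_band")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("blot table missing column(s): ", paste(miss, collapse = ", "))
  num <- c("v1_band", "v0a1_ip_band", "v0a1_input_band")
  if (any(vapply(measurements[num], function(v) any(v < 0), logical(1))))
    stop("band intensities must be >= 0")
  invisible(measurements)
}

#' Normalize V1 interaction bands to wild-type V0a1 IP signal
#'
#' Each sample's V1 band is divided by the mean V0a1 IP band over the
#' wild-type samples, putting all interaction readouts on the same
#' wild-type-referenced scale. Invariant under global rescaling of all
#' bands.
#'
#' @param measurements `data.frame` with columns `sample`, `genotype`
#'   (`"WT"`/`"MUT"`), `v1_band`, `v0a1_ip_band`, `v0a1_input_band`.
#' @param wt_label Genotype label of the reference group (default `"WT"`).
#' @return `measurements` with a `normalized_interaction` column.
#' @export
normalize_interaction <- function(measurements, wt_label = "WT") {
  check_blot_table(measurements)
  wt <- measurements$v0a1_ip_band[measurements$genotype == wt_label]
  if (!length(wt)) stop("no ", wt_label, " sample in table")
  ref <- mean(wt)
  if (ref <= 0) stop("mean wild-type V0a1 IP band is zero")
  measurements$normalized_interaction <- measurements$v1_band / ref
  measurements
}

#' Normalize total V1 bands to per-sample V0a1 input
#'
#' @param measurements Blot table (see [normalize_interaction()]).
#' @return `measurements` with a `normalized_total` column
#'   (`v1_band / v0a1_input_band`).
#' @export
normalize_total <- function(measurements) {
  check_blot_table(measurements)
  zero <- measurements$v0a1_input_band <= 0
  if (any(zero))
    stop("zero V0a1 input band for sample(s): ",
         paste(measurements$sample[zero], collapse = ", "))
  measurements$normalized_total <-
    measurements$v1_band / measurements$v0a1_input_band
  measurements
}

#' Percent reduction of the mutant group relative to wild type
#'
#' `(1 - mean(mut) / mean(wt)) * 100`; positive values mean the mutant
#' signal is reduced.
#'
#' @param wt_values,mut_values Numeric vectors of normalized values.
#' @return Percentage (single number).
#' @export
percent_reduction <- function(wt_values, mut_values) {
  if (!length(wt_values) || !length(mut_values))
    stop("both groups must be non-empty")
  mw <- mean(wt_values)
  if (mw <= 0) stop("mean of wild-type values must be > 0")
  (1 - mean(mut_values) / mw) * 100
}

#' Run the blot assembly analysis
#'
#' Interaction and total normalization, per-genotype percent reduction, and
#' Welch two-tailed comparisons (shared with the imaging statistics).
#'
#' @param measurements Blot table (see [normalize_interaction()]).
#' @param wt_label,mut_label Genotype labels.
#' @return List with the augmented table, `interaction_reduction_pct`,
#'   `total_reduction_pct`, and Welch comparisons for both readouts.
#' @export
run_assembly_analysis <- function(measurements, wt_label = "WT",
                                  mut_label = "MUT") {
  m <- normalize_total(normalize_interaction(measurements, wt_label))
  wt <- m$genotype == wt_label
  mut <- m$genotype == mut_label
  as_cells <- function(field) {
    data.frame(group = m$genotype, value = m[[field]])
  }
  welch <- function(field) {
    compare_groups(as_cells(field), "value", test = "welch")
  }
  list(measurements = m,
       interaction_reduction_pct =
         percent_reduction(m$normalized_interaction[wt],
                           m$normalized_interaction[mut]),
       total_reduction_pct =
         percent_reduction(m$normalized_total[wt],
                           m$normalized_total[mut]),
       interaction_test = welch("normalized_interaction"),
       total_test = welch("normalized_total"))
}
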