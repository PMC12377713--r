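#' @importFrom stats sd rnorm rpois runif rlnorm setNames p.adjust phyper
#'   t.test wilcox.test weighted.mean dnorm
#' @importFrom utils read.csv write.csv head packageVersion
#' @importFrom tools md5sum
NULL

# ---------------------------------------------------------------------------
# Sample design -------------------------------------------------------------

#' Build an IP sample design
#'
#' Describes which count-table columns hold which IP sample in the
#' dual-epitope-tag design: each sample is a (role, tag, replicate) triple,
#' where role is `"bait"` (the tagged protein of interest) or `"control"`
#' (the tagged irrelevant bait), and tag is one of two independent epitope
#' tags (e.g. Myc and V5). A complete design has exactly two replicates per
#' (role, tag) combination.
#'
#' @param sample Character vector of column names in the count table.
#' @param role `"bait"` or `"control"`, one per sample.
#' @param tag Tag system label, one per sample (exactly two distinct values).
#' @param replicate Positive integer replicate index within (role, tag).
#' @return A `data.frame` with class `"ip_design"`.
#' @export
ip_design <- function(sample, role, tag, replicate) {
  role <- match.arg(role, c("bait", "control"), several.ok = TRUE)
  if (length(unique(c(length(sample), length(role), length(tag),
                      length(replicate)))) != 1L)
    stop("sample, role, tag and replicate must have equal length")
  if (anyDuplicated(sample))
    stop("duplicate sample names in design")
  replicate <- as.integer(replicate)
  if (any(is.na(replicate)) || any(replicate < 1L))
    stop("replicate must be a positive integer")
  d <- data.frame(sample = as.character(sample), role = role,
                  tag = as.character(tag), replicate = replicate,
                  stringsAsFactors = FALSE)
  class(d) <- c("ip_design", "data.frame")
  d
}

#' The default dual-tag design used throughout
#'
#' Two tags x bait/control x two replicates = 8 samples, with column names
#' `<role>_<tag>_<replicate>`.
#'
#' @param tags Character vector of length 2 naming the tag systems.
#' @return An [ip_design()].
#' @export
default_design <- function(tags = c("tagA", "tagB")) {
  stopifnot(length(tags) == 2L)
  g <- expand.grid(replicate = 1:2, tag = tags, role = c("bait", "control"),
                   stringsAsFactors = FALSE)
  ip_design(sample = sprintf("%s_%s_%d", g$role, g$tag, g$replicate),
            role = g$role, tag = g$tag, replicate = g$replicate)
}

check_complete_design <- function(design) {
  tags <- unique(design$tag)
  if (length(tags) != 2L)
    stop("design must declare exactly two tag systems, got: ",
         paste(tags, collapse = ", "))
  tab <- table(design$role, design$tag)
  if (!all(dim(tab) == c(2L, 2L)) || !all(tab == 2L))
    stop("complete design requires exactly two replicates per ",
         "(role, tag) combination")
  invisible(design)
}

design_samples <- function(design, role, tag = NULL) {
  keep <- design$role == role
  if (!is.null(tag)) keep <- keep & design$tag == tag
  design$sample[keep]
}

# ---------------------------------------------------------------------------
# Spectral count tables -----------------------------------------------------

#' Construct a spectral-count table
#'
#' One row per protein: accession, gene symbol, molecular weight (kDa) and a
#' non-negative total spectrum count (TSC) for every sample declared in the
#' design.
#'
#' @param accession Character vector of unique protein accessions.
#' @param gene_symbol Character vector of gene symbols.
#' @param molecular_weight_kda Numeric vector of molecular weights in kDa
#'   (strictly positive).
#' @param counts Numeric matrix of TSCs, rows = proteins, columns named after
#'   the design samples.
#' @param design An [ip_design()].
#' @return An object of class `"spectral_count_table"`.
#' @export
spectral_count_table <- function(accession, gene_symbol, molecular_weight_kda,
                                 counts, design) {
  accession <- as.character(accession)
  if (anyDuplicated(accession))
    stop("duplicate accession(s): ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "))
  if (any(!is.finite(molecular_weight_kda)) || any(molecular_weight_kda <= 0))
    stop("molecular_weight must be > 0 for every protein; offending: ",
         paste(accession[!is.finite(molecular_weight_kda) |
                           molecular_weight_kda <= 0], collapse = ", "))
  counts <- as.matrix(counts)
  if (nrow(counts) != length(accession))
    stop("counts must have one row per accession")
  missing_cols <- setdiff(design$sample, colnames(counts))
  if (length(missing_cols))
    stop("counts missing columns for samples: ",
         paste(missing_cols, collapse = ", "))
  counts <- counts[, design$sample, drop = FALSE]
  if (anyNA(counts)) {
    idx <- which(is.na(counts), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing TSC for accession '%s', sample '%s'",
                 accession[idx[1L]], design$sample[idx[2L]]))
  }
  if (any(counts < 0))
    stop("negative TSCs are not allowed")
  rownames(counts) <- accession
  structure(list(
    info = data.frame(accession = accession,
                      gene_symbol = as.character(gene_symbol),
                      molecular_weight_kda = as.numeric(molecular_weight_kda),
                      stringsAsFactors = FALSE),
    counts = counts,
    design = design,
    imputed = FALSE,
    normalized = FALSE
  ), class = "spectral_count_table")
}

#' @export
print.spectral_count_table <- function(x, ...) {
  cat(sprintf("spectral_count_table: %d proteins x %d samples (%s%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$imputed) "zero-imputed, " else "raw, ",
              if (x$normalized) "MW-normalized" else "counts"))
  print(head(cbind(x$info, as.data.frame(x$counts)), 5L))
  if (nrow(x$counts) > 5L) cat("...\n")
  invisible(x)
}

#' @export
dim.spectral_count_table <- function(x) dim(x$counts)

subset_sct <- function(x, keep) {
  x$info <- x$info[keep, , drop = FALSE]
  rownames(x$info) <- NULL
  x$counts <- x$counts[keep, , drop = FALSE]
  x
}

#' Read a spectral-count table from delimited text
#'
#' Expects a header row naming, at minimum, the accession, gene-symbol and
#' molecular-weight columns plus one column per sample in `design`. Parsing
#' uses a decimal point regardless of locale. Missing cells, duplicate
#' accessions and negative or non-integer TSCs are rejected.
#'
#' @param path Path to a CSV (or TSV with `sep = "\t"`) file.
#' @param design An [ip_design()] mapping column names to samples.
#' @param accession_col,symbol_col,mw_col Names of the identifier columns.
#' @param sep Field separator.
#' @return A [spectral_count_table()].
#' @export
read_spectral_counts <- function(path, design,
                                 accession_col = "accession",
                                 symbol_col = "gene_symbol",
                                 mw_col = "molecular_weight_kda",
                                 sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE)
  need <- c(accession_col, symbol_col, mw_col, design$sample)
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols))
    stop("unknown column(s) requested but absent from file: ",
         paste(missing_cols, collapse = ", "))
  for (s in design$sample) {
    v <- df[[s]]
    bad <- which(is.na(v) | (is.character(v) & !nzchar(trimws(v))))
    if (length(bad))
      stop(sprintf("blank/missing TSC in row %d (accession '%s'), column '%s'",
                   bad[1L], df[[accession_col]][bad[1L]], s))
    v <- as.numeric(v)
    if (anyNA(v) || any(v < 0) || any(v != floor(v)))
      stop(sprintf("column '%s' contains negative or non-integer TSCs", s))
    df[[s]] <- v
  }
  spectral_count_table(accession = df[[accession_col]],
                       gene_symbol = df[[symbol_col]],
                       molecular_weight_kda = as.numeric(df[[mw_col]]),
                       counts = as.matrix(df[design$sample]),
                       design = design)
}

#' Write a spectral-count table to CSV
#'
#' @param x A [spectral_count_table()].
#' @param path Output path.
#' @export
write_spectral_counts <- function(x, path) {
  df <- cbind(x$info, as.data.frame(x$counts, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Channel images ------------------------------------------------------------

#' Construct a single-channel image
#'
#' A 2D non-negative intensity grid with a physical pixel size. Pixels are
#' addressed row-major with 0-based indices in reported centroids; areas are
#' pixel counts times `pixel_size_um^2`.
#'
#' @param values Numeric matrix of intensities (non-negative).
#' @param pixel_size_um Pixel edge length in micrometres (> 0).
#' @param channel_name Optional channel label.
#' @return An object of class `"channel_image"` (a matrix with attributes).
#' @export
channel_image <- function(values, pixel_size_um, channel_name = "") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("image values must be numeric")
  if (anyNA(values) || any(values < 0))
    stop("image intensities must be non-negative and finite")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  structure(values, pixel_size_um = as.numeric(pixel_size_um),
            channel_name = as.character(channel_name),
            class = c("channel_image", "matrix", "array"))
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("channel_image '%s': %d x %d px, %.4g um/px, range [%.4g, %.4g]\n",
              attr(x, "channel_name"), nrow(x), ncol(x),
              attr(x, "pixel_size_um"), min(x), max(x)))
  invisible(x)
}

pixel_size <- function(img) {
  ps <- attr(img, "pixel_size_um")
  if (is.null(ps)) stop("object carries no pixel_size_um attribute")
  ps
}

# rebuild a channel_image, preserving metadata of a template
as_channel <- function(values, template, channel_name = NULL) {
  channel_image(values, pixel_size(template),
                channel_name %||% attr(template, "channel_name") %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a binary mask
#'
#' @param values Logical matrix (or coercible 0/1 matrix).
#' @param pixel_size_um Pixel size in micrometres.
#' @return An object of class `"binary_mask"`.
#' @export
binary_mask <- function(values, pixel_size_um) {
  values <- as.matrix(values)
  storage.mode(values) <- "logical"
  if (anyNA(values)) stop("mask must not contain NA")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  structure(values, pixel_size_um = as.numeric(pixel_size_um),
            class = c("binary_mask", "matrix", "array"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %d x %d px, %.4g um/px, %d foreground px\n",
              nrow(x), ncol(x), attr(x, "pixel_size_um"), sum(x)))
  invisible(x)
}

mask_area_um2 <- function(mask) sum(mask) * pixel_size(mask)^2

#' Read a single-plane grayscale TIFF as a channel image
#'
#' Intensities are preserved bit-exactly (integer sample values for integer
#' TIFFs). Multi-plane or RGB input is rejected with a hint to split
#' channels upstream.
#'
#' @param path Path to a TIFF file.
#' @param pixel_size_um Physical pixel size in micrometres (> 0); TIFF
#'   metadata is not interpreted.
#' @param channel_name Optional channel label.
#' @return A [channel_image()].
#' @export
read_channel_image <- function(path, pixel_size_um, channel_name = "") {
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(planes) != 1L)
    stop("multi-plane TIFF: split channels/slices into single-plane ",
         "grayscale files before reading")
  m <- planes[[1L]]
  if (length(dim(m)) == 3L) {
    if (dim(m)[3L] == 1L) m <- m[, , 1L]
    else stop("RGB/multi-sample TIFF: split channels into single-plane ",
              "grayscale files before reading")
  }
  channel_image(m, pixel_size_um, channel_name)
}

#' Write a channel image to a 16-bit grayscale TIFF
#'
#' @param img A [channel_image()] with integer intensities in `[0, 65535]`.
#' @param path Output path.
#' @export
write_channel_image <- function(img, path) {
  if (max(img) > 65535) stop("intensities exceed 16-bit range")
  tiff::writeTIFF(unclass(img) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Contaminant lists ---------------------------------------------------------

#' Load a contaminant identifier list
#'
#' One identifier per line (accession or gene symbol); blank lines and lines
#' starting with `#` are ignored. With `path = NULL` the packaged default is
#' used: a constructed, CRAPome-style list of frequently co-purifying
#' proteins (keratins, serum proteins, proteases and similar frequent
#' flyers). It is a synthetic stand-in for study-specific contaminant
#' references and should be replaced when a curated list is available.
#'
#' @param path Path to a plain-text list, or `NULL` for the packaged default.
#' @return Character vector of identifiers, class `"contaminant_list"`.
#' @export
read_contaminant_list <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "contaminants_synthetic.txt",
                        package = "endoscore", mustWork = TRUE)
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  structure(unique(x), class = "contaminant_list")
}

# ---------------------------------------------------------------------------
# Result records ------------------------------------------------------------

#' Write analysis results as versioned JSON
#'
#' Output carries a schema version, the full parameter set used, and the
#' records themselves; [read_results()] round-trips it.
#'
#' @param records A data.frame (possibly empty) or list of records.
#' @param path Output path.
#' @param parameters Named list of parameters to echo verbatim.
#' @param analysis Short analysis label.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, parameters = list(),
                          analysis = "endoscore") {
  payload <- list(schema_version = "1.0",
                  analysis = analysis,
                  parameters = parameters,
                  n_records = if (is.data.frame(records)) nrow(records)
                              else length(records),
                  records = records)
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write results to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read results written by [write_results()]
#'
#' @param path Path to a results JSON file.
#' @return List with `schema_version`, `analysis`, `parameters`, `records`.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
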