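# Shared fixture builders; everything is generated in code at test time.

# A toy dual-tag count table built from explicit per-protein counts.
# counts: named list accession -> numeric vector of 8 TSCs in the order of
# default_design() columns (bait_tagA_1, bait_tagA_2, bait_tagB_1,
# bait_tagB_2, control_tagA_1, control_tagA_2, control_tagB_1,
# control_tagB_2); mw: named numeric.
toy_sct <- function(counts, mw, symbols = NULL) {
  design <- default_design()
  m <- do.call(rbind, counts)
  colnames(m) <- design$sample
  acc <- names(counts)
  spectral_count_table(acc, symbols %||% acc, mw[acc], m, design)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# count-row helper: scalars are duplicated, length-2 vectors taken as the
# two replicates, in design column order (bait tagA, bait tagB, controls)
row8 <- function(baitA, baitB, ctrlA, ctrlB) {
  rep2 <- function(x) if (length(x) == 1L) rep(x, 2L) else x
  c(rep2(baitA), rep2(baitB), rep2(ctrlA), rep2(ctrlB))
}

# build a channel image of zeros with disks painted at given centers (1-based)
disk_image <- function(shape, centers, radius_px, amplitude = 100,
                       pixel_size_um = 0.1, base = 0) {
  m <- matrix(base, shape[1], shape[2])
  if (length(centers)) {
    cen <- matrix(unlist(centers), ncol = 2, byrow = TRUE)
    for (i in seq_len(nrow(cen))) {
      rr <- pmax(1, floor(cen[i, 1] - radius_px)):
        pmin(shape[1], ceiling(cen[i, 1] + radius_px))
      cc <- pmax(1, floor(cen[i, 2] - radius_px)):
        pmin(shape[2], ceiling(cen[i, 2] + radius_px))
      d2 <- outer((rr - cen[i, 1])^2, (cc - cen[i, 2])^2, `+`)
      m[rr, cc][d2 <= radius_px^2] <- amplitude
    }
  }
  channel_image(m, pixel_size_um)
}

disk_bin_mask <- function(shape, centers, radius_px, pixel_size_um = 0.1) {
  img <- disk_image(shape, centers, radius_px, amplitude = 1,
                    pixel_size_um = pixel_size_um)
  binary_mask(unclass(img) > 0, pixel_size_um)
}

# independent hypergeometric upper-tail oracle by direct term summation
hyper_tail_oracle <- function(a, K, n, N) {
  ks <- a:min(n, K)
  if (a > min(n, K)) return(0)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# write a toy counts CSV for I/O tests; returns the path
write_toy_counts_csv <- function(path, blank_cell = FALSE) {
  design <- default_design()
  hdr <- c("accession", "gene_symbol", "molecular_weight_kda", design$sample)
  rows <- list(
    c("P1", "GENE1", "52.1", as.character(c(12, 8, 6, 5, 1, 0, 2, 1))),
    c("P2", "GENE2", "100", as.character(c(4, 3, 11, 2, 0, 0, 1, 0))),
    c("P3", "GENE3", "30.5", as.character(c(20, 25, 18, 22, 3, 2, 4, 5))))
  if (blank_cell) rows[[2]][5] <- ""   # bait_tagA_2 of P2
  writeLines(c(paste(hdr, collapse = ","),
               vapply(rows, paste, "", collapse = ",")), path)
  path
}
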