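# Dual-epitope-tag IP-MS enrichment scoring.
#
# The same bait is expressed with two independent epitope tags and pulled
# down with two antibodies (two biological replicates each), alongside
# tag-matched irrelevant-bait controls. Enrichment is scored per protein as
# fold changes (FC) of mean molecular-weight-normalized spectral counts,
# bait over control, once per tag and once combined over all samples; only
# proteins enriched in BOTH tag systems and combined survive, which
# suppresses tag- and antibody-specific artifacts.

#' Filter low-abundance proteins, per tag dataset
#'
#' A protein is retained in a tag's dataset according to its raw bait TSCs:
#' with `rule = "and"` (default) iff the maximum over that tag's two bait
#' duplicates is `>= min_dup` AND the maximum over all four bait samples is
#' `>= min_any`; with `rule = "or"` either condition suffices (the reading
#' in which removal requires failing both). Retained proteins keep all
#' sample columns. Subsequent processing runs on each tag dataset
#' separately.
#'
#' @param table A raw [spectral_count_table()] with a complete two-tag,
#'   two-replicate bait design.
#' @param min_dup Per-tag duplicate threshold (default 5 TSCs).
#' @param min_any All-bait-samples threshold (default 10 TSCs).
#' @param rule `"and"` or `"or"`; how the two retention clauses combine.
#' @return Named list of two [spectral_count_table()]s, one per tag.
#' @export
filter_low_abundance <- function(table, min_dup = 5, min_any = 10,
                                 rule = c("and", "or")) {
  rule <- match.arg(rule)
  check_complete_design(table$design)
  tags <- unique(table$design$tag)
  all_bait <- design_samples(table$design, "bait")
  if (length(all_bait) != 4L) stop("missing a bait replicate")
  max_any <- apply(table$counts[, all_bait, drop = FALSE], 1L, max)
  out <- lapply(tags, function(tg) {
    dup <- design_samples(table$design, "bait", tg)
    if (length(dup) != 2L) stop("missing a bait replicate for tag ", tg)
    max_dup <- apply(table$counts[, dup, drop = FALSE], 1L, max)
    keep <- if (rule == "and") max_dup >= min_dup & max_any >= min_any
            else                max_dup >= min_dup | max_any >= min_any
    subset_sct(table, keep)
  })
  names(out) <- tags
  out
}

#' Impute zero spectral counts
#'
#' Every TSC equal to 0 is replaced by `pseudo` (default 0.1) so that fold
#' changes remain finite; nonzero TSCs are unchanged.
#'
#' @param table A [spectral_count_table()].
#' @param pseudo Value replacing zeros.
#' @return The table with zeros imputed.
#' @export
impute_zero_counts <- function(table, pseudo = 0.1) {
  table$counts[table$counts == 0] <- pseudo
  table$imputed <- TRUE
  table
}

#' Normalize spectral counts by molecular weight
#'
#' Divides every (possibly imputed) TSC by the protein's molecular weight in
#' kDa, yielding counts/kDa. Larger proteins yield more peptides and hence
#' more spectra at equal molarity; MW normalization removes that size bias.
#'
#' @param table A [spectral_count_table()].
#' @return The table on the counts/kDa scale.
#' @export
mw_normalize <- function(table) {
  mw <- table$info$molecular_weight_kda
  bad <- !is.finite(mw) | mw <= 0
  if (any(bad))
    stop("molecular weight absent or <= 0 for: ",
         paste(table$info$accession[bad], collapse = ", "))
  table$counts <- table$counts / mw
  table$normalized <- TRUE
  table
}

#' Per-tag and combined fold changes
#'
#' On imputed, MW-normalized per-tag tables: the per-tag FC is the
#' arithmetic mean of that tag's two bait duplicates over the mean of its
#' two control duplicates. The combined FC, computed for proteins present in
#' both tag datasets, is the mean over all four bait samples over the mean
#' over all four control samples.
#'
#' @param tag_tables Named list of two per-tag [spectral_count_table()]s
#'   (from [filter_low_abundance()], then [impute_zero_counts()] and
#'   [mw_normalize()] applied to each).
#' @return A `data.frame` of fold-change records, one row per protein that
#'   appears in at least one tag dataset: accession, gene symbol, per-tag
#'   mean bait/control normalized abundances, `fc_<tag>` (NA when absent
#'   from that tag dataset), `fc_combined` (NA unless present in both),
#'   `passed_<tag>` flags.
#' @export
fold_changes <- function(tag_tables) {
  if (length(tag_tables) != 2L || is.null(names(tag_tables)))
    stop("tag_tables must be a named list of two per-tag tables")
  tags <- names(tag_tables)
  for (tt in tag_tables) {
    if (!tt$imputed || !tt$normalized)
      stop("tables must be zero-imputed and MW-normalized before fold changes")
    if (!any(tt$design$role == "control"))
      stop("a tag dataset has no control samples")
  }
  accs <- unique(unlist(lapply(tag_tables, function(t) t$info$accession)))
  info <- do.call(rbind, lapply(tag_tables, function(t) t$info))
  info <- info[!duplicated(info$accession), , drop = FALSE]
  rownames(info) <- info$accession
  rec <- data.frame(accession = accs,
                    gene_symbol = info[accs, "gene_symbol"],
                    stringsAsFactors = FALSE)
  for (tg in tags) {
    tt <- tag_tables[[tg]]
    bait <- rowMeans(tt$counts[, design_samples(tt$design, "bait", tg),
                               drop = FALSE])
    ctrl <- rowMeans(tt$counts[, design_samples(tt$design, "control", tg),
                               drop = FALSE])
    idx <- match(tt$info$accession, rec$accession)
    rec[[paste0("mean_bait_", tg)]] <- NA_real_
    rec[[paste0("mean_control_", tg)]] <- NA_real_
    rec[[paste0("fc_", tg)]] <- NA_real_
    rec[[paste0("mean_bait_", tg)]][idx] <- bait
    rec[[paste0("mean_control_", tg)]][idx] <- ctrl
    rec[[paste0("fc_", tg)]][idx] <- bait / ctrl
    rec[[paste0("passed_", tg)]] <- !is.na(rec[[paste0("fc_", tg)]])
  }
  # combined FC over all four bait / all four control samples, for proteins
  # surviving the abundance filter in both tag datasets
  both <- Reduce(intersect, lapply(tag_tables, function(t) t$info$accession))
  rec$fc_combined <- NA_real_
  if (length(both)) {
    bait_sum <- ctrl_sum <- setNames(numeric(length(both)), both)
    nb <- nc <- 0L
    for (tg in tags) {
      tt <- tag_tables[[tg]]
      bcols <- design_samples(tt$design, "bait", tg)
      ccols <- design_samples(tt$design, "control", tg)
      m <- match(both, tt$info$accession)
      bait_sum <- bait_sum + rowSums(tt$counts[m, bcols, drop = FALSE])
      ctrl_sum <- ctrl_sum + rowSums(tt$counts[m, ccols, drop = FALSE])
      nb <- nb + length(bcols); nc <- nc + length(ccols)
    }
    rec$fc_combined[match(both, rec$accession)] <-
      (bait_sum / nb) / (ctrl_sum / nc)
  }
  rec$is_candidate <- NA
  rec$is_contaminant <- NA
  rownames(rec) <- NULL
  rec
}

#' Select candidate interactors by fold-change threshold
#'
#' A protein is a candidate iff all of `fc_<tagA>`, `fc_<tagB>` and
#' `fc_combined` are populated (it survived abundance filtering in both tag
#' datasets) and each is `>= fc_threshold` (inclusive).
#'
#' @param records Fold-change records from [fold_changes()].
#' @param fc_threshold Minimum fold change (default 2).
#' @return `records` with `is_candidate` set.
#' @export
select_candidates <- function(records, fc_threshold = 2) {
  fc_cols <- grep("^fc_", names(records), value = TRUE)
  stopifnot(length(fc_cols) >= 3L)
  m <- as.matrix(records[fc_cols])
  records$is_candidate <- !apply(is.na(m), 1L, any) &
    apply(m >= fc_threshold, 1L, all)
  records
}

#' Remove common contaminants from the candidate set
#'
#' Matching is case-insensitive and exact, on accession first and gene
#' symbol as fallback. Removals are reported via `message()` with the
#' matched identifier and recorded in `is_contaminant`; contaminants lose
#' candidate status.
#'
#' @param records Records from [select_candidates()].
#' @param contaminants A [read_contaminant_list()] vector (possibly empty).
#' @return `records` with `is_contaminant` set and candidates pruned.
#' @export
remove_contaminants <- function(records, contaminants = character(0)) {
  cl <- toupper(as.character(contaminants))
  by_acc <- toupper(records$accession) %in% cl
  by_sym <- toupper(records$gene_symbol) %in% cl
  records$is_contaminant <- by_acc | by_sym
  hit <- which(records$is_contaminant & records$is_candidate %in% TRUE)
  for (i in hit) {
    message(sprintf("contaminant removed: %s (matched %s)",
                    records$accession[i],
                    if (by_acc[i]) "accession" else "gene symbol"))
  }
  records$is_candidate <- records$is_candidate & !records$is_contaminant
  records
}

#' Category over-representation test (one-sided Fisher)
#'
#' For each annotation term, forms the 2x2 table (candidate & in-term,
#' candidate & not, background-only & in-term, background-only & not) and
#' computes the one-sided (over-representation) Fisher exact p-value, i.e.
#' the upper hypergeometric tail, with Benjamini-Hochberg adjustment across
#' terms. Fold enrichment is (hits_in_set/set_size) /
#' (hits_in_background/background_size).
#'
#' @param candidates Character vector of candidate identifiers.
#' @param annotation `data.frame` with columns `id`, `term_id` and
#'   optionally `term_name`, mapping identifiers to terms.
#' @param background Character vector of background identifiers
#'   (superset of `candidates`).
#' @return `data.frame` with one row per term: counts, `fold_enrichment`,
#'   `p_value`, `adjusted_p`, sorted by `p_value`.
#' @export
enrichment_test <- function(candidates, annotation, background) {
  candidates <- unique(as.character(candidates))
  background <- unique(as.character(background))
  missing <- setdiff(candidates, background)
  if (length(missing))
    stop("candidate(s) not in background: ",
         paste(head(missing, 5L), collapse = ", "))
  stopifnot(all(c("id", "term_id") %in% names(annotation)))
  annotation <- annotation[annotation$id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(candidates)
  terms <- unique(annotation$term_id)
  res <- lapply(terms, function(tm) {
    ids <- unique(annotation$id[annotation$term_id == tm])
    K <- length(ids)                       # hits in background
    a <- sum(candidates %in% ids)          # hits in set
    p <- fisher_overrep_p(a, K, n, N)
    fe <- if (K == 0L) NA_real_ else (a / n) / (K / N)
    nm <- if ("term_name" %in% names(annotation))
      annotation$term_name[match(tm, annotation$term_id)] else tm
    data.frame(term_id = tm, term_name = nm,
               n_hits_in_set = a, n_set = n,
               n_hits_in_background = K, n_background = N,
               fold_enrichment = fe, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$adjusted_p <- p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# One-sided over-representation p: P(X >= a) for X ~ Hypergeom(N, K, n).
fisher_overrep_p <- function(a, K, n, N) {
  stopifnot(all(a >= 0), all(K >= 0), all(n >= 0),
            all(N >= pmax(K, n)), all(a <= pmin(K, n)))
  phyper(a - 1, K, N - K, n, lower.tail = FALSE)
}

#' Run the full dual-tag interactome pipeline
#'
#' Stages, in fixed order: abundance filter (per tag) -> zero imputation ->
#' MW normalization -> duplicate averaging and fold changes -> candidate
#' selection (per-tag and combined FC >= threshold) -> contaminant removal.
#' Optionally runs [enrichment_test()] on the surviving candidates against
#' all table proteins as background.
#'
#' @param table Raw [spectral_count_table()].
#' @param fc_threshold Fold-change threshold (default 2).
#' @param min_dup,min_any,filter_rule Passed to [filter_low_abundance()].
#' @param pseudo Zero-imputation value (default 0.1).
#' @param contaminants Contaminant identifiers (default: packaged list; use
#'   `character(0)` for none).
#' @param annotation Optional annotation table for [enrichment_test()].
#' @return List with `records` (all fold-change records), `candidates`
#'   (candidate subset), `n_candidates`, `enrichment` (or NULL) and the
#'   `parameters` used.
#' @export
run_interactome_pipeline <- function(table, fc_threshold = 2,
                                     min_dup = 5, min_any = 10,
                                     filter_rule = "and", pseudo = 0.1,
                                     contaminants = read_contaminant_list(),
                                     annotation = NULL) {
  tag_tables <- filter_low_abundance(table, min_dup = min_dup,
                                     min_any = min_any, rule = filter_rule)
  tag_tables <- lapply(tag_tables, function(tt)
    mw_normalize(impute_zero_counts(tt, pseudo = pseudo)))
  records <- fold_changes(tag_tables)
  records <- select_candidates(records, fc_threshold = fc_threshold)
  records <- remove_contaminants(records, contaminants)
  cand <- records[records$is_candidate %in% TRUE, , drop = FALSE]
  enr <- NULL
  if (!is.null(annotation) && nrow(cand))
    enr <- enrichment_test(cand$accession, annotation,
                           background = table$info$accession)
  list(records = records,
       candidates = cand,
       n_candidates = nrow(cand),
       enrichment = enr,
       parameters = list(fc_threshold = fc_threshold, min_dup = min_dup,
                         min_any = min_any, filter_rule = filter_rule,
                         pseudo = pseudo,
                         n_contaminant_ids = length(contaminants)))
}
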