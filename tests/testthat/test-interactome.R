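# Dual-tag enrichment scoring: filtering, imputation, normalization, fold
# changes, candidate selection, contaminant removal, over-representation.

mw1 <- c(P1 = 50, P2 = 50, P3 = 50)

test_that("abundance filter applies the per-tag duplicate and global rules", {
  tab <- toy_sct(list(P1 = row8(c(12, 8), c(6, 5), c(1, 1), c(1, 1)),
                      P2 = row8(c(4, 3), c(11, 2), c(1, 1), c(1, 1)),
                      P3 = row8(c(4, 4), c(4, 4), c(1, 1), c(1, 1))),
                 mw1)
  out <- filter_low_abundance(tab)
  # P2 fails the tagA duplicate rule (max 4 < 5) so under "and" it only
  # survives in the tagB dataset; P3 fails everywhere (max 4 < 5, all < 10)
  expect_setequal(out$tagA$info$accession, "P1")
  expect_setequal(out$tagB$info$accession, c("P1", "P2"))
  expect_false("P3" %in% out$tagA$info$accession)
  expect_false("P3" %in% out$tagB$info$accession)
  # retained proteins keep every sample column
  expect_equal(ncol(out$tagA$counts), 8L)

  # the "or" reading rescues P2 in tagA via the global >= 10 clause
  out_or <- filter_low_abundance(tab, rule = "or")
  expect_setequal(out_or$tagA$info$accession, c("P1", "P2"))
})

test_that("per-tag duplicate clause alone decides under rule = 'and' when the
           global clause passes", {
  tab <- toy_sct(list(P1 = row8(c(4, 3), c(11, 12), c(1, 1), c(1, 1))),
                 c(P1 = 50))
  out <- filter_low_abundance(tab)
  expect_false("P1" %in% out$tagA$info$accession)  # dup max 4 < 5
  expect_true("P1" %in% out$tagB$info$accession)
})

test_that("zero imputation replaces exactly the zeros with 0.1", {
  tab <- toy_sct(list(P1 = c(0, 5, 2, 0, 0, 0, 0, 0)), c(P1 = 50))
  imp <- impute_zero_counts(tab)
  expect_equal(unname(imp$counts[1, ]), c(0.1, 5, 2, 0.1, 0.1, 0.1, 0.1, 0.1))
})

test_that("MW normalization divides by kDa and rejects bad weights", {
  tab <- toy_sct(list(P1 = rep(10, 8)), c(P1 = 50))
  norm <- mw_normalize(tab)
  expect_equal(unname(norm$counts[1, 1]), 0.2)
  imp <- impute_zero_counts(toy_sct(list(P1 = rep(0, 8)), c(P1 = 100)))
  expect_equal(unname(mw_normalize(imp)$counts[1, 1]), 0.001)
  bad <- toy_sct(list(P1 = rep(1, 8)), c(P1 = 50))
  bad$info$molecular_weight_kda <- 0
  expect_error(mw_normalize(bad), "P1")
})

test_that("fold changes follow mean(bait)/mean(control), per tag and combined", {
  # bait norm means 4, control norm means 2 in every tag -> all FCs 2
  tab <- toy_sct(list(P1 = row8(c(200, 200), c(200, 200),
                                c(100, 100), c(100, 100))), c(P1 = 50))
  tags <- lapply(filter_low_abundance(tab), function(t)
    mw_normalize(impute_zero_counts(t)))
  rec <- fold_changes(tags)
  expect_equal(rec$fc_tagA, 2)
  expect_equal(rec$fc_tagB, 2)
  expect_equal(rec$fc_combined, 2)

  # bait = control everywhere -> all FCs 1
  tab1 <- toy_sct(list(P1 = rep(30, 8)), c(P1 = 50))
  rec1 <- fold_changes(lapply(filter_low_abundance(tab1), function(t)
    mw_normalize(impute_zero_counts(t))))
  expect_equal(c(rec1$fc_tagA, rec1$fc_tagB, rec1$fc_combined), c(1, 1, 1))
})

test_that("fold change with zero-imputed controls matches hand arithmetic", {
  # bait normalized [0.30, 0.50], controls all zero-imputed to 0.1 over
  # MW 100 -> 0.001: FC = mean(0.30, 0.50)/0.001 = 400
  tab <- toy_sct(list(P1 = c(30, 50, 30, 50, 0, 0, 0, 0)), c(P1 = 100))
  rec <- fold_changes(lapply(filter_low_abundance(tab), function(t)
    mw_normalize(impute_zero_counts(t))))
  expect_equal(rec$fc_tagA, 400)
  expect_equal(rec$fc_tagB, 400)
  expect_equal(rec$fc_combined, 400)
})

test_that("candidate selection is a conjunction with inclusive thresholds", {
  rec <- data.frame(accession = c("A", "B", "C"),
                    gene_symbol = c("A", "B", "C"),
                    fc_tagA = c(2.5, 2.5, 2.0),
                    fc_tagB = c(2.1, 1.9, 2.0),
                    fc_combined = c(2.3, 2.2, 2.0))
  out <- select_candidates(rec, 2)
  expect_equal(out$is_candidate, c(TRUE, FALSE, TRUE))
  # threshold nesting: threshold 1 candidates contain threshold 2 candidates
  out1 <- select_candidates(rec, 1)
  expect_true(all(out$accession[out$is_candidate] %in%
                    out1$accession[out1$is_candidate]))
})

test_that("contaminant matching is case-insensitive on accession then symbol", {
  rec <- data.frame(accession = c("Q123", "P04264", "Q999"),
                    gene_symbol = c("krt1", "WEIRD", "CLEAN"),
                    fc_tagA = 3, fc_tagB = 3, fc_combined = 3)
  rec <- select_candidates(rec)
  out <- suppressMessages(
    remove_contaminants(rec, c("KRT1", "p04264")))
  expect_equal(out$is_contaminant, c(TRUE, TRUE, FALSE))
  expect_equal(out$is_candidate, c(FALSE, FALSE, TRUE))
  # empty list is the identity
  out0 <- remove_contaminants(rec, character(0))
  expect_equal(out0$is_candidate, rec$is_candidate)
})

test_that("over-representation p equals the hypergeometric tail and fold
           enrichment follows its definition", {
  # 2x2 table a=10 in-set-in-term, b=90, c=20, d=880
  set <- sprintf("s%03d", 1:100)
  bg_only <- sprintf("b%03d", 1:900)
  bg <- c(set, bg_only)
  ann <- data.frame(id = c(set[1:10], bg_only[1:20]), term_id = "T1")
  res <- enrichment_test(set, ann, bg)
  expect_equal(res$p_value, hyper_tail_oracle(10, 30, 100, 1000),
               tolerance = 1e-12)
  expect_equal(res$fold_enrichment, (10 / 100) / (30 / 1000))

  # a term annotating every background gene has fold enrichment 1
  ann_all <- data.frame(id = bg, term_id = "ALL")
  expect_equal(enrichment_test(set, ann_all, bg)$fold_enrichment, 1)

  # zero candidate hits: fold enrichment 0 and p = 1
  ann_none <- data.frame(id = bg_only[1:50], term_id = "NONE")
  res0 <- enrichment_test(set, ann_none, bg)
  expect_equal(res0$fold_enrichment, 0)
  expect_equal(res0$p_value, 1)

  expect_error(enrichment_test(c(set, "missing"), ann, bg),
               "not in background")
})

test_that("the pipeline recovers planted interactors and is order-invariant", {
  sim <- sim_spectral_counts(n_background = 100, n_interactors = 10,
                             enrichment_factor = 10, mean_control_tsc = 20,
                             dropout_prob = 0, seed = 11)
  res <- suppressMessages(run_interactome_pipeline(sim$table))
  planted <- sim$truth$accession[sim$truth$is_interactor]
  expect_true(all(planted %in% res$candidates$accession))
  # occasional Poisson-noise false positives are tolerated, but few
  expect_lte(sum(!(res$candidates$accession %in% planted)), 2L)

  # permutation invariance over row order
  perm <- sample(nrow(sim$table$counts))
  tab2 <- spectral_count_table(sim$table$info$accession[perm],
                               sim$table$info$gene_symbol[perm],
                               sim$table$info$molecular_weight_kda[perm],
                               sim$table$counts[perm, ], sim$table$design)
  res2 <- suppressMessages(run_interactome_pipeline(tab2))
  expect_setequal(res2$candidates$accession, res$candidates$accession)

  # every protein with bait = control gives no candidates
  flat <- toy_sct(list(P1 = rep(20, 8), P2 = rep(40, 8)), c(P1 = 50, P2 = 80))
  expect_equal(suppressMessages(run_interactome_pipeline(flat))$n_candidates,
               0L)
})

test_that("fold changes are scale-invariant and monotone in the counts", {
  base <- c(30, 50, 20, 40, 10, 10, 5, 15)
  fc_of <- function(v, mw = 50) {
    tab <- toy_sct(list(P1 = v), c(P1 = mw))
    rec <- fold_changes(lapply(filter_low_abundance(tab), function(t)
      mw_normalize(impute_zero_counts(t))))
    c(rec$fc_tagA, rec$fc_tagB, rec$fc_combined)
  }
  expect_equal(fc_of(base * 3), fc_of(base))

  f0 <- fc_of(base)
  for (i in 1:4) {   # bait positions
    up <- base; up[i] <- up[i] + 7
    expect_true(all(fc_of(up) >= f0 - 1e-12))
  }
  for (i in 5:8) {   # control positions
    up <- base; up[i] <- up[i] + 7
    expect_true(all(fc_of(up) <= f0 + 1e-12))
  }
})
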