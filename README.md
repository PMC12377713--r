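# endoscore

Quantification pipelines for endolysosomal cell biology. The package is
aimed at labs that combine affinity-purification mass spectrometry with
fluorescence imaging of the endosome–lysosome system and want the
downstream number-crunching — not the acquisition — to be scripted,
tested and reproducible. It covers four procedures that usually live in
spreadsheets and interactive image tools:

* **Dual-epitope-tag IP-MS enrichment scoring.** The same bait is pulled
  down via two independent epitope tags (e.g. Myc and V5, two biological
  replicates each) alongside tag-matched irrelevant-bait controls. Per
  protein, total spectrum counts are filtered for low abundance, zeros are
  imputed with 0.1, counts are normalized by molecular weight, and fold
  changes FC = mean(bait)/mean(control) are computed per tag and combined
  over all samples. Candidate interactors must reach the threshold
  (default ≥ 2, inclusive) in *both* tag systems and combined, and must
  not match a contaminant list. A one-sided Fisher exact test with
  Benjamini–Hochberg adjustment scores annotation-term over-representation
  in the candidate set.
* **Puncta colocalization.** Channels are segmented
  (denoise → background-subtract → threshold → watershed-split →
  minimum-area filter) and overlap is quantified as Manders-style area
  fractions, area(A∩B)/area(A) and area(A∩B)/area(B), with the two-marker
  (LAMP1 ∧ CTSD) mature-lysosome definition built in.
* **Ratiometric endolysosomal pH (FIRE-pHly-style).** Cell-body masking on
  the green channel, per-channel preprocessing, Laplacian-of-Gaussian
  bright-spot detection at a fixed physical diameter on the pH-stable red
  channel, per-punctum green/red ratios, per-cell summaries, puncta-count
  study weights w_i = 10·n_i/N_total (summing to 10 across the study), and
  Welch or exact Mann–Whitney group comparisons with cells as units.
* **Blot densitometry for V-ATPase assembly.** V1-subunit band
  intensities normalized to wild-type V0a1 IP signal (interaction) or
  per-sample V0a1 input (totals), and the percent reduction
  (1 − mean(MUT)/mean(WT)) × 100.

Seeded synthetic-data generators (`sim_spectral_counts()`,
`sim_coloc_images()`, `sim_phly_cohort()`, `sim_blot_table()`) produce
inputs with exact ground truth for every stage, so the whole chain is
testable without any external data.

## Worked example

```r
library(endoscore)

# --- IP-MS enrichment on a synthetic table with 20 planted interactors ---
sim <- sim_spectral_counts(n_background = 500, n_interactors = 20,
                           enrichment_factor = 10, seed = 1)
res <- run_interactome_pipeline(sim$table)
res$n_candidates
#> [1] 20
head(res$candidates[, c("accession", "gene_symbol",
                        "fc_tagA", "fc_tagB", "fc_combined")], 3)
#>   accession gene_symbol fc_tagA fc_tagB fc_combined
#> 1  SIM00001        INT1   10.07  11.275      10.635
#> 2  SIM00002        INT2   10.22   9.966      10.089
#> 3  SIM00003        INT3   10.93   9.200       9.981

# --- ratiometric pH quantification of one synthetic cell ---
cohort <- sim_phly_cohort(n_cells_per_group = c(WT = 1, MUT = 1), seed = 1)
cell <- cohort$cells[[1]]
q <- quantify_phly_cell(cell$green, cell$red, cell_id = "WT_01",
                        group = "WT", intensity_threshold = 20)
q$summary
#>   cell_id group cell_body_area_um2 n_puncta density_per_100um2 mean_gr
#> 1   WT_01    WT              284.2       12              4.222  0.7374
#>   mean_area_um2
#> 1           1.8
cohort$truth$true_gr[1]
#> [1] 0.7374
```

All 20 planted interactors are recovered with their ~10-fold enrichment,
and the measured per-cell green/red ratio (0.7374) matches the planted
ratio of that synthetic cell. Per-cell summaries feed `assign_weights()`
and `compare_groups()` for group-level statistics.

A command-line entry point wrapping the same functions ships in
`inst/exec/endoscore`, with subcommands `interactome`, `coloc`, `phly`,
`phly-compare`, `assembly` and `simulate`; every run writes a JSON result
with a manifest (version, parameters, input digests, seed).

## Documentation

The methods vignette
(`vignettes/endolysosomal-quantification.Rmd`) documents the models and
assumptions, every tunable parameter with units and defaults, the
numerical conventions (boundary handling, connectivity, tie-breaking,
degenerate inputs), what the synthetic generators do and do not emulate,
and known limitations.
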