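# uwshap

Biomarker discovery from label-free tear proteomics by model explanation,
with uncertainty-weighted Shapley attributions.

## The problem

Meibomian gland dysfunction (MGD) is the leading cause of evaporative dry
eye disease. Tear-film samples analysed by label-free LC-MS yield a relative
protein quantification table — one peak area per protein per patient, with
two special states: a missing entry means the protein was not detected, and
a recorded 0 marks *protein inference* (a quantification that cannot be
unambiguously assigned to the protein). Given such a table plus a clinical
MGD severity grade (levels 2–4) per patient, the question is which proteins
track disease severity.

`uwshap` implements a complete, reproducible pipeline for that question:

1. **Preprocessing** — exclusion of severity levels with too few patients,
   removal of contaminant proteins by name (keratins except 18/19,
   dermcidins/dermacolins, trypsins), removal of never-detected proteins,
   encoding of the special states (0 → 1 first, then missing → 0), and
   `log1p` + per-feature standardization.
2. **Severity classifiers** — gradient-boosted ensembles of single-split
   stumps (`num_leaves = 2` regularization), one multiclass model over the
   levels present plus one one-vs-rest model per level, with class-balanced
   weighting for the imbalanced cohort. Models are deliberately evaluated on
   their own training data (balanced accuracy, F1, MCC): the aim is to
   describe the cohort, not to predict new patients.
3. **Shapley attributions** — exact per-sample, per-class, per-feature
   Shapley values of the model margin. For stump ensembles the ensemble is
   additive across features, so the attribution is exact:
   φ<sub>j</sub>(x) = Σ<sub>trees t splitting on j</sub> ( t(x) − E<sub>background</sub>[t] ),
   and Σ<sub>j</sub> φ<sub>j</sub>(x) + base = margin(x) to machine
   precision. A brute-force 2<sup>p</sup> subset-enumeration oracle
   (`exact_shapley`) verifies this independently.
4. **Uncertainty weighting** — the novel step. Predictions are grouped by a
   confidence threshold τ = 0.6: *Positive* (correct, p > τ), *Negative*
   (incorrect, p > τ), *Borderline* (p ≤ τ). Attribution values are then
   rescaled:

   - Positive: φ′ = φ / (1 − p)
   - Negative: φ′ = φ · (1 − p)
   - Borderline: φ′ = φ

   so confident correct predictions dominate the global ranking. Two
   aggregation modes exist: `incl_bl` (weight everything, keep borderline
   samples unchanged; needs ground truth) and `excl_bl` (drop borderline
   samples, change nothing else; works without ground truth). Global
   importance is the sum of absolute weighted values; rankings are compared
   top-k (default 15) with newly entering proteins flagged.
5. **Differential abundance** — the classical comparator: per-protein
   one-way ANOVA on log values, maximum fold change on raw group means,
   Benjamini–Hochberg FDR, significance at FDR ≤ 1 % and fold change ≥ 2,
   plus pairwise rank-sum tests between levels.
6. **Synthetic cohorts** — because clinical tear proteomes are rarely
   shareable, `simulate_cohort()` generates cohorts with the same
   structure: right-skewed log-normal abundances, abundance-dependent
   (missing-not-at-random) detection, inference zeros, named contaminants
   and planted severity effects, fully deterministic given one seed.

## Worked example

```r
library(uwshap)

cfg <- sim_config(counts_per_level = c("2" = 31, "3" = 126, "4" = 76),
                  n_proteins = 300,
                  planted_effects = list(planted_effect(1, c("4" = 1)),
                                         planted_effect(2, c("3" = 0.5, "4" = 1))),
                  seed = 42)
cohort <- simulate_cohort(cfg)
cohort$quant
#> quant_table: 233 samples x 305 proteins
#>   not detected (NA): 10020 entries; inference zeros: 613 entries

prep <- preprocess_quant(cohort$quant, cohort$clinical)
fit <- severity_model(prep$matrix, prep$clinical$mgd_level,
                      kind = "multiclass", seed = 42)
evaluate_training_fit(fit, prep$matrix$values, prep$clinical$mgd_level)
#> balanced accuracy 0.930 | F1 0.906 | MCC 0.843

shap <- attributions(fit, prep$matrix$values)
prob <- predict(fit, prep$matrix$values, type = "prob")
cls  <- predict(fit, prep$matrix$values, type = "class")
recs <- group_predictions(cls,
                          prob[cbind(seq_len(nrow(prob)), max.col(prob, "first"))],
                          true_labels = prep$clinical$mgd_level)
table(recs$group)
#> Borderline   Negative   Positive
#>        123          3        107

w <- weight_attributions(shap, recs, prob, mode = "incl_bl")
aggregate_importance(w, k = 5)
#> feature_ranking: top 5 of 301 features
#>  rank accession     score
#>     1   SYN0001 328.22049
#>     2   SYN0002 145.58360
#>     3   SYN0116  72.75701
#>     4   SYN0188  60.65974
#>     5   SYN0138  53.90309
```

The two planted severity markers (`SYN0001`, `SYN0002`) head the weighted
ranking; the scores are summed absolute weighted attributions on the margin
scale. `run_pipeline()` executes all of the above — four models, unweighted
and weighted rankings in both modes, rank comparisons and the
differential-abundance table — writing every output as TSV/JSON plus a
manifest with MD5 checksums, byte-identical across runs with the same seed.

## Caveats

The fitted models describe the training cohort only and must not be used
for diagnosis. See the methods vignette
(`vignettes/uncertainty-weighted-attributions.Rmd`) for the model,
parameter and design details.
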