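---
title: "Uncertainty-weighted Shapley attributions for tear-proteome severity models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-weighted Shapley attributions for tear-proteome severity models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uwshap)
```

## Overview

`uwshap` analyses label-free tear-proteome quantification tables to find
proteins associated with the severity of meibomian gland dysfunction (MGD).
Severity classifiers are fitted to the full cohort, per-sample Shapley
attributions explain them, and a confidence-based weighting scheme
re-ranks the globally important proteins. A classical per-protein
differential-abundance analysis runs alongside as a comparator. This
vignette documents the model, every tunable parameter, the numerical
choices, and what the synthetic-data tests do and do not establish.

## Data model and preprocessing

The input is a samples × proteins matrix of relative quantifications (peak
areas, arbitrary units) with two special states:

* `NA` — the protein was not detected in the sample;
* `0` — *protein inference*: a measurement that cannot be unambiguously
  assigned to this protein.

Preprocessing runs in a fixed order, and the order matters:

1. `exclude_sparse_levels()` removes severity grades with fewer than
   `min_count = 2` patients (a single-patient level supports no group
   statistics).
2. `filter_contaminants()` drops proteins whose *name* matches a
   contaminant pattern, case-insensitively: keratins, dermcidins,
   dermacolins and trypsins — skin proteins and the digestion reagent —
   with keratins 18 and 19 protected by a keep list (keep wins over
   remove). Matching on names rather than accessions is deliberate:
   contaminant families share naming, not accession structure.
3. `drop_undetected()` removes proteins never detected in any sample.
4. `encode_special_values()` rewrites `0 → 1` **first** (inference flags)
   and **then** `NA → 0` (undetected means zero peak area). Reversing the
   order would merge the two states.
5. `log_standardize()` applies `log1p` and per-feature standardization.

Two conventions here are choices rather than givens. The log transform must
handle exact zeros; `log1p` (natural) is used because it maps 0 to 0, is
monotone, and needs no ad-hoc pseudo-count — the base only rescales
standardized features, so downstream results are invariant to it.
Standardization uses the population (divide-by-n) standard deviation, the
machine-learning scaler convention; constant features map to all-zero
columns with a recorded sd of 0 instead of erroring. The fitted means/sds
are stored so new data can be encoded bit-identically
(`apply_log_standardize()`).

## Severity classifiers

`severity_model()` fits gradient-boosted tree ensembles in which every tree
is a **single-split stump** (`max_depth = 1`, i.e. two leaves) — a strong
regularizer appropriate for p ≫ n proteomics tables. Remaining boosting
parameters are library defaults: learning rate 0.1, 100 rounds. Four models
cover the analysis: one multiclass model over the severity levels present
and one one-vs-rest binary model per level. Class imbalance is handled by
class-balanced sample weights (multiclass) or the negative/positive weight
ratio (binary). Training is single-threaded and seeded, so fits are
reproducible.

The models are trained **and evaluated on the same data** — a deliberate
"microscope" design: the goal is to describe which proteins structure the
cohort, not to estimate out-of-sample performance. Training-set balanced
accuracy (mean per-class recall), F1 (support-weighted for multiclass,
positive-class for binary) and the Matthews correlation coefficient are
reported by `evaluate_training_fit()`; with hundreds of features and
boosted stumps these are typically near 1 on synthetic cohorts and say
nothing about generalization. Probability ties at argmax resolve to the
lowest class label so reports are deterministic.

One numerical detail: class margins are accumulated from the parsed tree
leaf values in double precision (the booster is consulted only to route
samples to leaves). The library's own prediction accumulates in single
precision, which would cap the attribution identity below at ~1e-7;
the double-precision path makes it exact, and tests assert agreement with
the library margins at 1e-5.

## Exact Shapley attributions

`attributions()` computes per-sample, per-class, per-feature Shapley values
of the model **margin** (log-odds scale), under the interventional
expectation over a background set (default: the training data). The margin
is the native additive scale of a tree ensemble; probabilities are used
only for the grouping step below, and the two choices are independent.

Because every tree is a stump, the ensemble is additive across features and
the Shapley value has a closed form: for feature j,
`phi_j(x) = sum over trees t splitting on j of (t(x_j) - mean_background(t))`.
This is exact — no path heuristics — so the implementation satisfies, to
machine precision:

* **local accuracy**: `sum_j phi_j(x) + base = margin(x)`;
* **null player**: features never split on get exactly 0;
* **symmetry and linearity** (inherited from the Shapley axioms).

An independent brute-force oracle, `exact_shapley()`, evaluates the classic
Shapley formula over all 2^p coalitions (capped at p = 12) for any value
function; `model_value_function()` builds the interventional value function
of a fitted model. The test suite verifies oracle equivalence on dozens of
randomly fitted ensembles. For one-vs-rest models the negative class is
exposed as the negation of the positive class.

## Uncertainty weighting

Each prediction is grouped by the probability of its predicted class
against a threshold τ (default 0.6, exposed as a parameter; comparisons are
strict, so p = τ exactly is Borderline):

* **Positive** — correct and p > τ;
* **Negative** — incorrect and p > τ;
* **Borderline** — p ≤ τ, whatever the correctness.

Attribution values are rescaled per sample: Positive values become
`phi / (1 - p)`, Negative values `phi * (1 - p)`, Borderline values pass
through. Dividing by `1 - p` (not multiplying by p) makes the amplification
grow with confidence; at τ = 0.6 every Positive entry is scaled by more
than 2.5 and every Negative entry by less than 0.4, and no weight can flip
a sign. Probabilities are clipped to `[1e-6, 1 - 1e-6]` first, because
boosted ensembles emit probabilities arbitrarily close to 1 and the
Positive weight would otherwise be unbounded.

For multiclass models the weighting is applied per class: the **true**
class of a confidently predicted sample is upweighted and every other class
downweighted, each class using its own predicted probability (for a correct
prediction the upweighted class is the predicted one). Using each class's
own probability — including a possibly sub-threshold probability for the
true class of a Negative sample — is an assumption; the scheme defines the
weights only through "the predicted probability", and per-class
probabilities are the only per-class quantity available.

Two aggregation modes produce global rankings:

* `incl_bl` — weight all confident samples, keep Borderline ones unchanged
  (requires ground truth);
* `excl_bl` — drop Borderline samples and change nothing else (no ground
  truth needed).

Global importance is `sum over samples (and classes) of |weighted value|`.
The absolute sum is the field-standard global measure; a signed-sum variant
(`signed = TRUE`) is provided because "the sum of the SHAP values" is
ambiguous, but absolute is the default since signed sums let opposite-signed
contributions cancel. Ties break lexicographically by accession for
reproducible reports. `compare_rankings()` reports, over the top-k window
(default k = 15, a practical reading-list size), the proteins newly
entering the weighted ranking and every rank shift.

Two degenerate identities pin the scheme down and are tested exactly:
τ = 1 makes everything Borderline, so `incl_bl` returns the unweighted
ranking; a cohort with no Borderline samples makes `excl_bl` return the
unweighted ranking.

## Differential abundance

`differential_abundance()` is the classical route: per-protein one-way
ANOVA across severity levels on `log1p` values, maximum fold change
(largest/smallest group mean on the raw scale, pseudo-count 1 against zero
means), Benjamini–Hochberg FDR, and a significance flag at FDR ≤ 1 % *and*
fold change ≥ 2. ANOVA on the log scale and fold change on the raw scale is
a choice — abundance data are multiplicative, but fold-change thresholds
are conventionally quoted on raw means. The ANOVA is vectorized across
proteins (group-sum algebra); the tests assert equality with
`stats::oneway.test(var.equal = TRUE)` per protein. Degenerate proteins
follow fixed conventions: no variance at all gives p = 1, zero
within-group variance with real group differences gives p = 0.
`pairwise_level_test()` compares two levels with a two-sided rank-sum test
(normal approximation with tie correction, so identical groups give
exactly p = 1; a Welch t-test is available as a switch since the choice of
pairwise test is an assumption). Significance is marked at p < 0.05 and
p-values in [0.05, 0.06) are additionally flagged borderline.

## The synthetic cohort generator

`simulate_cohort()` emulates the cohort structure the analysis targets.
Defaults (each a configurable parameter of `sim_config()`):

* **Cohort**: 31/126/76 patients at levels 2/3/4 (233 total).
* **Features**: 2000 proteins plus five named contaminants (keratin 1,
  keratin 18 as a keep-list probe, dermcidin, trypsin-1, putative
  trypsin-6).
* **Abundances**: per-protein baselines log-normal with meanlog 12 and
  sdlog 2 (natural-log scale) — medians around 1.6e5 with a range spanning
  several orders of magnitude, the right-skew and width typical of
  label-free peak areas; within-protein between-sample noise sdlog 0.5
  (≈ 65 % CV, a realistic biological-plus-technical spread).
* **Missingness**: missing-not-at-random logistic detection,
  `P(detect) = plogis(0.8 * (log(x) - 9))` — low-abundance proteins are
  preferentially censored (≈ 15 % missing overall at the defaults), the
  standard LC-MS detection-limit mechanism.
* **Inference zeros**: detected entries recorded as 0 with probability
  0.01.
* **Planted effects**: `planted_effect()` shifts a protein's group mean by
  a specified log2 amount per severity level, before missingness.

All randomness flows from one seed through fixed per-stage derived seeds,
so identical configurations give bit-identical cohorts. Since no
distributional ground truth for the real quantifications is available
beyond their skewness and range, realism is asserted only through the
property suite (null calibration, effect recovery, monotone
missingness-by-abundance).

## What the tests show — and what they cannot

Problem sizes in the shipped suite were chosen to keep a full run around
half a minute: oracle equivalence on 50 random ensembles of up to 8
features and 20 stumps; planted-marker recovery on 20 cohorts of 230
patients × 200 proteins with 10 planted markers at |log2FC| = 1 (the median
run recovers ≥ 8 in the unweighted top-20 and ≥ 7 in each weighted
top-20); null FDR behaviour over 200 small cohorts.

Two calibration checks deliberately disable the detection-limit censoring
(`midpoint = -Inf`): the uniformity of null ANOVA p-values (KS < 0.05 over
2000 proteins) and the FC = 4 power check (flagged in ≥ 95 % of runs at
n = 30/group). On clean continuous cohorts both hold comfortably. On
MNAR-censored cohorts they do not: the missing → 0 encoding zero-inflates
the log values, which inflates within-group variance and costs most of the
power at FDR 1 % for proteins near the detection limit (and perturbs
p-value uniformity at the few-percent level). That is a real property of
running ANOVA on zero-encoded label-free data, not an implementation
artifact — the acceptance script's study-condition run reports it honestly
(planted FC = 2 markers top the attribution rankings yet none pass the
differential filter). The mean false-discovery-proportion check, by
contrast, is run on fully censored cohorts and still passes (≈ 0.005
against a 0.03 bound): the encoding costs power, not FDR control.

Passing on synthetic cohorts shows the machinery is correct under the
generator's assumptions (log-normal abundances, independent proteins,
logistic MNAR detection). Real tear proteomes have correlated proteins,
batch structure and non-log-normal tails; nothing here validates the
biology of any ranked protein, and the fitted models must not be used
diagnostically.

## Known limitations

* Attributions are exact only because trees are stumps; deeper trees would
  need a full tree-traversal algorithm (out of scope).
* Probability-vs-margin scale: grouping uses probabilities while
  attributions live on the margin scale; both are defensible and the pair
  is the documented convention here.
* The multiclass weighting of an incorrect prediction upweights the true
  class by its own (possibly small) probability — an interpretation the
  scheme's wording leaves open.
* `excl_bl` rankings change only through sample exclusion; with few
  borderline samples they are close to the unweighted ranking by
  construction.
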