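#' Per-protein one-way ANOVA across severity levels
#'
#' Vectorized one-way fixed-effects ANOVA F-test, one p-value per protein,
#' computed on log-transformed values. When a protein shows neither
#' between- nor within-group variance the test is undefined and p = 1 by
#' convention; zero within-group variance with real between-group
#' differences yields p = 0.
#'
#' @param values Samples x proteins matrix on the log scale.
#' @param labels Severity levels aligned with the rows (vector or
#'   [clinical_table()]).
#' @return Named numeric vector of p-values.
#' @export
anova_per_protein <- function(values, labels) {
  if (inherits(labels, "clinical_table")) labels <- labels$mgd_level
  if (length(labels) != nrow(values)) stop("labels do not align with rows")
  counts <- table(labels)
  g <- length(counts)
  n <- nrow(values)
  if (g < 2) stop("need at least two groups")
  if (any(counts < 2)) stop("every group needs at least two samples")

  grand <- colMeans(values)
  vc <- sweep(values, 2, grand)
  ss_tot <- colSums(vc^2)
  gm <- rowsum(values, labels) / as.numeric(counts)   # g x p group means
  gmc <- sweep(gm, 2, grand)
  ss_between <- colSums(gmc^2 * as.numeric(counts))
  ss_within <- pmax(ss_tot - ss_between, 0)

  f <- (ss_between / (g - 1)) / (ss_within / (n - g))
  p <- stats::pf(f, g - 1, n - g, lower.tail = FALSE)
  tol <- 1e-12 * pmax(ss_tot, 1)
  p[ss_within <= tol & ss_between > tol] <- 0
  p[ss_tot <= tol] <- 1
  names(p) <- colnames(values)
  p
}

#' Maximum fold change between group means
#'
#' Ratio of the largest to the smallest group mean per protein, computed on
#' the raw scale with a pseudo-count guarding against zero means.
#'
#' @param values Samples x proteins matrix on the raw scale (values >= 0).
#' @param labels Group labels aligned with rows.
#' @param pseudo Pseudo-count added to both means (default 1).
#' @return Named numeric vector of ratios >= 1.
#' @export
max_fold_change <- function(values, labels, pseudo = 1) {
  if (inherits(labels, "clinical_table")) labels <- labels$mgd_level
  if (any(values < 0, na.rm = TRUE)) stop("raw values must be >= 0")
  counts <- table(labels)
  gm <- rowsum(values, labels) / as.numeric(counts)
  fc <- (apply(gm, 2, max) + pseudo) / (apply(gm, 2, min) + pseudo)
  names(fc) <- colnames(values)
  fc
}

#' Flag significant proteins by FDR and fold change
#'
#' Adjusts the ANOVA p-values by Benjamini-Hochberg and flags proteins with
#' `q <= q_max` and maximum fold change `>= fc_min` — the standard
#' label-free significance rule (defaults: FDR 1%, fold change 2).
#'
#' @param results Data frame with columns `accession`, `anova_p`,
#'   `max_fold_change`.
#' @param q_max FDR threshold.
#' @param fc_min Fold-change threshold.
#' @return The data frame with added `q` and `significant` columns.
#' @export
significant_proteins <- function(results, q_max = 0.01, fc_min = 2) {
  stopifnot(all(c("accession", "anova_p", "max_fold_change") %in%
                  names(results)))
  results$q <- stats::p.adjust(results$anova_p, method = "BH")
  results$significant <- results$q <= q_max &
    results$max_fold_change >= fc_min
  if (nrow(results) == 0) results$significant <- logical(0)
  results
}

#' Differential abundance across severity levels
#'
#' The classical comparator to the model-explanation route: per-protein
#' one-way ANOVA on `log1p` values, maximum fold change on raw group means,
#' Benjamini-Hochberg FDR, and the joint significance flag.
#'
#' @param quant An encoded [quant_table()] (no missing entries; see
#'   [encode_special_values()]).
#' @param labels Severity levels aligned with samples.
#' @param q_max,fc_min Significance thresholds.
#' @param pseudo Pseudo-count for the fold change.
#' @return Data frame: `accession`, `name`, `anova_p`, `q`,
#'   `max_fold_change`, `significant`.
#' @export
differential_abundance <- function(quant, labels, q_max = 0.01, fc_min = 2,
                                   pseudo = 1) {
  v <- quant$values
  if (anyNA(v)) stop("encode special values before testing")
  p <- anova_per_protein(log1p(v), labels)
  fc <- max_fold_change(v, labels, pseudo)
  res <- data.frame(accession = quant$proteins$accession,
                    name = quant$proteins$name,
                    anova_p = unname(p),
                    max_fold_change = unname(fc),
                    stringsAsFactors = FALSE)
  res <- significant_proteins(res, q_max, fc_min)
  res[, c("accession", "name", "anova_p", "q", "max_fold_change",
          "significant")]
}

#' Pairwise severity-level comparison for one protein
#'
#' Two-sided test between two severity levels, by default the Mann-Whitney
#' rank-sum test (normal approximation with tie correction; identical
#' groups give p = 1). Significance is marked at
#' p < 0.05; p-values in [0.05, 0.06) are reported as borderline.
#'
#' @param values Numeric vector of one protein's quantifications.
#' @param labels Severity levels aligned with `values`.
#' @param level_a,level_b The two levels to compare.
#' @param method `"ranksum"` (default) or `"ttest"` (Welch).
#' @return List: `p_value`, `significant` (p < 0.05), `borderline`
#'   (0.05 <= p < 0.06), `marker` (`"*"` when significant, else `""`).
#' @export
pairwise_level_test <- function(values, labels, level_a, level_b,
                                method = c("ranksum", "ttest")) {
  method <- match.arg(method)
  if (inherits(labels, "clinical_table")) labels <- labels$mgd_level
  xa <- values[labels == level_a]
  xb <- values[labels == level_b]
  if (length(xa) < 2 || length(xb) < 2)
    stop("both levels need at least two samples")
  p <- if (method == "ranksum") {
    suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE,
                                        correct = FALSE)$p.value)
  } else {
    stats::t.test(xa, xb)$p.value
  }
  if (is.nan(p)) p <- 1   # fully tied groups: no evidence of a difference
  list(p_value = p,
       significant = p < 0.05,
       borderline = p >= 0.05 && p < 0.06,
       marker = if (p < 0.05) "*" else "")
}
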