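#' Group predictions by confidence and correctness
#'
#' Each prediction is assigned to one of three groups using the probability
#' of the predicted class and a confidence threshold `tau` (default 0.6):
#' `Positive` if correct with probability > tau, `Negative` if incorrect
#' with probability > tau, `Borderline` otherwise (probability <= tau,
#' whatever the correctness). Without true labels only confidence can be
#' judged, and records are grouped `Confident` / `Borderline` — enough for
#' the borderline-exclusion aggregation mode.
#'
#' @param predicted_labels Vector of predicted class labels.
#' @param predicted_probabilities Probability of each predicted class.
#' @param true_labels Optional vector of true labels.
#' @param tau Confidence threshold in (0, 1].
#' @param sample_ids Optional sample identifiers.
#' @return Data frame of class `prediction_records` with columns
#'   `sample_id`, `true_label`, `predicted_label`, `predicted_probability`,
#'   `group`.
#' @export
group_predictions <- function(predicted_labels, predicted_probabilities,
                              true_labels = NULL, tau = 0.6,
                              sample_ids = NULL) {
  n <- length(predicted_labels)
  if (length(predicted_probabilities) != n)
    stop("misaligned prediction vectors")
  if (!is.null(true_labels) && length(true_labels) != n)
    stop("misaligned true labels")
  if (tau <= 0 || tau > 1) stop("`tau` must lie in (0, 1]")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(n))
  confident <- predicted_probabilities > tau
  if (is.null(true_labels)) {
    group <- ifelse(confident, "Confident", "Borderline")
    true_labels <- rep(NA, n)
  } else {
    group <- ifelse(confident,
                    ifelse(predicted_labels == true_labels,
                           "Positive", "Negative"),
                    "Borderline")
  }
  structure(data.frame(sample_id = sample_ids,
                       true_label = true_labels,
                       predicted_label = predicted_labels,
                       predicted_probability = predicted_probabilities,
                       group = group,
                       stringsAsFactors = FALSE),
            class = c("prediction_records", "data.frame"))
}

#' Uncertainty-weight a single attribution value
#'
#' The weighting scheme rescales an attribution by the model's predicted
#' probability `p`: `Positive` values are amplified to `original / (1 - p)`,
#' `Negative` values shrunk to `original * (1 - p)`, and `Borderline` (or
#' `Confident`) values pass through unchanged. Probabilities are clipped to
#' `[eps, 1 - eps]` so near-certain predictions cannot produce infinite
#' weights. The weighting never changes the sign of a value.
#'
#' @param original Numeric attribution value(s).
#' @param p Predicted probability(ies), recycled against `original`.
#' @param group `"Positive"`, `"Negative"`, `"Borderline"` or `"Confident"`.
#' @param eps Clipping constant (default 1e-6).
#' @return Weighted value(s).
#' @export
weight_value <- function(original, p, group, eps = 1e-6) {
  p <- pmin(pmax(p, eps), 1 - eps)
  factor <- ifelse(group == "Positive", 1 / (1 - p),
                   ifelse(group == "Negative", 1 - p, 1))
  original * factor
}

#' Uncertainty-weight an attribution set
#'
#' Two aggregation modes are supported. `incl_bl` keeps every sample and
#' reweights the confidently predicted ones: for any non-borderline sample
#' the true class is upweighted by `1 / (1 - p_c)` and every other class
#' downweighted by `(1 - p_c)`, each class using its own predicted
#' probability; borderline samples pass through unchanged. (For a correct
#' prediction the upweighted true class is the predicted class.) This mode
#' requires ground-truth labels. `excl_bl` simply drops the borderline
#' samples and leaves the remaining attributions unchanged — no ground
#' truth needed.
#'
#' @param attr An [attributions()] result.
#' @param records A [group_predictions()] data frame aligned with the
#'   samples of `attr`.
#' @param prob_matrix Samples x classes probability matrix (columns ordered
#'   as `attr$class_labels`); required for `incl_bl`.
#' @param mode `"incl_bl"` or `"excl_bl"`.
#' @param eps Probability clipping constant.
#' @return Object of class `weighted_attribution_set`: the (possibly
#'   subsetted) array of weighted values plus the matching records and the
#'   mode tag.
#' @export
weight_attributions <- function(attr, records, prob_matrix = NULL,
                                mode = c("incl_bl", "excl_bl"),
                                eps = 1e-6) {
  mode <- match.arg(mode)
  vals <- attr$values
  n <- dim(vals)[1]
  if (nrow(records) != n) stop("records do not align with attribution samples")

  if (mode == "excl_bl") {
    keep <- records$group != "Borderline"
    if (!any(keep)) stop("no samples retained: all predictions are borderline")
    out <- vals[keep, , , drop = FALSE]
    records <- records[keep, , drop = FALSE]
  } else {
    if (any(records$group == "Confident") || anyNA(records$true_label))
      stop("incl_bl weighting requires ground-truth labels")
    if (is.null(prob_matrix)) stop("incl_bl weighting needs `prob_matrix`")
    if (nrow(prob_matrix) != n || ncol(prob_matrix) != dim(vals)[2])
      stop("`prob_matrix` does not align with the attribution set")
    p <- pmin(pmax(prob_matrix, eps), 1 - eps)
    out <- vals
    labels <- attr$class_labels
    for (s in seq_len(n)) {
      if (records$group[s] == "Borderline") next
      up <- match(records$true_label[s], labels)
      for (ci in seq_along(labels)) {
        f <- if (ci == up) 1 / (1 - p[s, ci]) else (1 - p[s, ci])
        out[s, ci, ] <- out[s, ci, ] * f
      }
    }
  }
  structure(list(values = out, records = records, mode = mode,
                 class_labels = attr$class_labels,
                 feature_names = attr$feature_names),
            class = "weighted_attribution_set")
}

#' @export
print.weighted_attribution_set <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("weighted_attribution_set (%s): %d samples x %d classes x %d features\n",
              x$mode, d[1], d[2], d[3]))
  print(table(x$records$group))
  invisible(x)
}

#' Aggregate attributions into a global feature ranking
#'
#' The importance of a feature is the sum over retained samples (and, for
#' multiclass, over classes) of the absolute attribution values; with
#' `signed = TRUE` the magnitude of the signed sum is used instead. Features
#' are ranked by decreasing score with lexicographic tie-breaking by
#' accession.
#'
#' @param w A [weight_attributions()] result or an unweighted
#'   [attributions()] set.
#' @param class_of_interest Optional single class label restricting the
#'   aggregation to one class slice.
#' @param k Report cutoff stored with the ranking (default 15).
#' @param signed Use the signed-sum variant (default absolute sum).
#' @return Data frame of class `feature_ranking` with columns `rank`,
#'   `accession`, `score`, ordered by rank; attribute `k` carries the
#'   cutoff.
#' @export
aggregate_importance <- function(w, class_of_interest = NULL, k = 15,
                                 signed = FALSE) {
  vals <- w$values
  if (dim(vals)[1] == 0) stop("no retained samples to aggregate")
  if (!is.null(class_of_interest)) {
    ci <- match(class_of_interest, w$class_labels)
    if (is.na(ci)) stop("unknown class label")
    vals <- vals[, ci, , drop = FALSE]
  }
  score <- if (signed) {
    abs(apply(vals, 3, sum))
  } else {
    apply(abs(vals), 3, sum)
  }
  acc <- w$feature_names
  ord <- order(-score, acc)
  out <- data.frame(rank = seq_along(acc),
                    accession = acc[ord],
                    score = unname(score[ord]),
                    stringsAsFactors = FALSE)
  structure(out, class = c("feature_ranking", "data.frame"), k = k)
}

#' @export
print.feature_ranking <- function(x, ...) {
  k <- min(attr(x, "k") %||% 15, nrow(x))
  cat(sprintf("feature_ranking: top %d of %d features\n", k, nrow(x)))
  print.data.frame(utils::head(x, k), row.names = FALSE)
  invisible(x)
}

#' Compare two feature rankings
#'
#' Reports, for the top-k window, the accessions newly entering ranking `b`
#' relative to ranking `a` (the entries a report would flag) and the rank
#' shift of every feature in either top-k.
#'
#' @param a,b [aggregate_importance()] rankings over the same feature set.
#' @param k Window size; must not exceed the length of either ranking.
#' @return List of class `rank_comparison` with `k`, `new_in_b` (character
#'   vector, in `b`'s rank order) and `shifts` (data frame: `accession`,
#'   `rank_a`, `rank_b`, `shift = rank_a - rank_b`).
#' @export
compare_rankings <- function(a, b, k = 15) {
  if (k > nrow(a) || k > nrow(b)) stop("`k` exceeds a ranking's length")
  top_a <- a$accession[seq_len(k)]
  top_b <- b$accession[seq_len(k)]
  new_in_b <- top_b[!top_b %in% top_a]
  in_either <- union(top_a, top_b)
  shifts <- data.frame(accession = in_either,
                       rank_a = match(in_either, a$accession),
                       rank_b = match(in_either, b$accession),
                       stringsAsFactors = FALSE)
  shifts$shift <- shifts$rank_a - shifts$rank_b
  shifts <- shifts[order(shifts$rank_b), , drop = FALSE]
  rownames(shifts) <- NULL
  structure(list(k = k, new_in_b = new_in_b, shifts = shifts),
            class = "rank_comparison")
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat(sprintf("rank_comparison over top %d\n", x$k))
  if (length(x$new_in_b)) {
    cat("  new entries:", paste(x$new_in_b, collapse = ", "), "\n")
  } else {
    cat("  no new entries\n")
  }
  print(x$shifts, row.names = FALSE)
  invisible(x)
}
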