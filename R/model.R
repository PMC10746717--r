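#' One-vs-rest label encoding
#'
#' @param levels Integer vector of severity levels.
#' @param target_level Level to encode as the positive class.
#' @return Integer vector of 0/1.
#' @export
binarize_labels <- function(levels, target_level) {
  if (!target_level %in% levels)
    stop("target level ", target_level, " absent from the labels")
  as.integer(levels == target_level)
}

#' Fit a gradient-boosted severity classifier
#'
#' Fits a boosted ensemble of single-split stumps (two leaves per tree, the
#' strongest regularization a tree admits) to predict MGD severity from a
#' preprocessed protein matrix — either one multiclass model over the levels
#' present or a one-vs-rest binary model for a single level. Class imbalance
#' is handled by class-balanced sample weights (binary: positive-class
#' weight equal to the negative/positive ratio). Remaining boosting
#' parameters are library defaults (learning rate 0.1, 100 rounds).
#' Training is deterministic given `seed` (single-threaded).
#'
#' @param x A [log_standardize()] result or a numeric samples x features
#'   matrix with column names.
#' @param levels Integer severity levels aligned with the rows of `x`.
#' @param kind `"multiclass"` (all levels jointly) or `"one_vs_rest"`.
#' @param target_level Positive-class level, required for one-vs-rest.
#' @param nrounds Number of boosting rounds (stumps per class).
#' @param learning_rate Shrinkage applied to each stump.
#' @param imbalance_weighting Use class-balanced weights (default TRUE).
#' @param seed Integer seed.
#' @return Object of class `severity_model` with, among others, elements
#'   `booster` (the fitted ensemble), `class_labels` (ascending; for
#'   one-vs-rest `c(0, 1)` with 1 = target level) and `training_data`
#'   (kept as the default attribution background).
#' @seealso [predict.severity_model()], [evaluate_training_fit()],
#'   [attributions()]
#' @export
severity_model <- function(x, levels,
                           kind = c("multiclass", "one_vs_rest"),
                           target_level = NULL,
                           nrounds = 100, learning_rate = 0.1,
                           imbalance_weighting = TRUE, seed = 1L) {
  kind <- match.arg(kind)
  x <- as_feature_matrix(x)
  levels <- as.integer(levels)
  if (nrow(x) != length(levels)) stop("`x` rows and `levels` do not align")

  if (kind == "multiclass") {
    classes <- sort(unique(levels))
    if (length(classes) < 2) stop("need at least two classes to fit a model")
    y <- match(levels, classes) - 1L
    w <- NULL
    if (imbalance_weighting) {
      freq <- table(y)
      w <- as.numeric(length(y) / (length(freq) * freq[as.character(y)]))
    }
    params <- list(objective = "multi:softprob",
                   num_class = length(classes))
  } else {
    if (is.null(target_level)) stop("one_vs_rest needs `target_level`")
    y <- binarize_labels(levels, target_level)
    if (length(unique(y)) < 2) stop("need at least two classes to fit a model")
    classes <- c(0L, 1L)
    w <- NULL
    params <- list(objective = "binary:logistic")
    if (imbalance_weighting)
      params$scale_pos_weight <- sum(y == 0) / sum(y == 1)
  }
  params <- c(params, list(max_depth = 1L, eta = learning_rate,
                           nthread = 1L, base_score = 0.5,
                           seed = as.integer(seed)))
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, weight = w)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = nrounds, verbose = 0)
  ensemble <- build_ensemble(booster, kind, length(classes), x)
  structure(list(booster = booster,
                 ensemble = ensemble,
                 kind = kind,
                 class_labels = classes,
                 target_level = target_level,
                 feature_names = colnames(x),
                 nrounds = nrounds,
                 params = params,
                 seed = as.integer(seed),
                 n_train = nrow(x),
                 training_data = x),
            class = "severity_model")
}

as_feature_matrix <- function(x) {
  if (inherits(x, "preprocessed_matrix")) x <- x$values
  if (!is.matrix(x) || is.null(colnames(x)))
    stop("`x` must be a numeric matrix with feature (column) names")
  x
}

check_features <- function(model, x) {
  x <- as_feature_matrix(x)
  if (!all(model$feature_names %in% colnames(x)))
    stop("`x` lacks features the model was trained on")
  x[, model$feature_names, drop = FALSE]
}

#' Predict from a severity model
#'
#' @param object A [severity_model()].
#' @param newdata Feature matrix (or [log_standardize()] result).
#' @param type `"prob"` for the samples x classes probability matrix
#'   (columns ordered by ascending class label, rows summing to 1),
#'   `"class"` for the predicted label (probability ties go to the lowest
#'   class label), `"margin"` for raw per-class margins (log-odds scale).
#'   Margins are accumulated from the tree leaf values in double precision
#'   (the booster itself is used only to route samples to leaves), so the
#'   Shapley decomposition reproduces them to machine precision.
#' @param ... Unused.
#' @return Matrix or vector as per `type`.
#' @export
predict.severity_model <- function(object, newdata,
                                   type = c("prob", "class", "margin"),
                                   ...) {
  type <- match.arg(type)
  x <- check_features(object, newdata)
  m <- ensemble_margins(object, x)
  if (object$kind == "one_vs_rest") {
    m <- cbind(-m[, 1], m[, 1])
  }
  colnames(m) <- as.character(object$class_labels)
  rownames(m) <- rownames(x)
  if (type == "margin") return(m)
  if (object$kind == "one_vs_rest") {
    p1 <- stats::plogis(m[, 2])
    prob <- cbind(1 - p1, p1)
    dimnames(prob) <- dimnames(m)
  } else {
    e <- exp(m - apply(m, 1, max))
    prob <- e / rowSums(e)
  }
  if (type == "prob") return(prob)
  object$class_labels[max.col(prob, ties.method = "first")]
}

#' @export
print.severity_model <- function(x, ...) {
  cat("severity_model (boosted stumps)\n")
  if (x$kind == "multiclass") {
    cat(sprintf("  multiclass over levels {%s}\n",
                paste(x$class_labels, collapse = ",")))
  } else {
    cat(sprintf("  one-vs-rest, target level %s\n", x$target_level))
  }
  cat(sprintf("  %d boosting rounds, eta %.3g, %d training samples, %d features\n",
              x$nrounds, x$params$eta, x$n_train, length(x$feature_names)))
  invisible(x)
}

#' @export
summary.severity_model <- function(object, ...) {
  print(object)
  tt <- tree_table(object)
  used <- unique(tt$Feature[tt$Feature != "Leaf"])
  cat(sprintf("  features used by the ensemble: %d\n", length(used)))
  invisible(list(features_used = used))
}

#' Classification metrics from predicted and true labels
#'
#' Balanced accuracy (mean per-class recall over classes present in the
#' truth), F1 score (positive class for binary problems, class-support
#' weighted average for multiclass) and the Matthews correlation
#' coefficient (multiclass generalization; 0 when undefined, e.g. for a
#' constant predictor).
#'
#' @param truth,pred Vectors of true and predicted labels.
#' @param f1 `"binary"` (F1 of `positive`) or `"weighted"`.
#' @param positive Positive class label for binary F1.
#' @return List of class `training_metrics`: `balanced_accuracy`, `f1`,
#'   `mcc`.
#' @export
classification_metrics <- function(truth, pred,
                                   f1 = c("weighted", "binary"),
                                   positive = NULL) {
  f1_mode <- match.arg(f1)
  classes <- sort(unique(c(truth, pred)))
  cm <- table(factor(truth, classes), factor(pred, classes))
  # balanced accuracy: mean recall over classes with support
  support <- rowSums(cm)
  recall <- diag(cm) / support
  bal_acc <- mean(recall[support > 0])
  # F1 per class
  prec_den <- colSums(cm)
  f1_class <- vapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    den <- support[i] + prec_den[i]
    if (den == 0) return(0)
    2 * tp / den
  }, numeric(1))
  if (f1_mode == "binary") {
    if (is.null(positive)) stop("binary F1 needs `positive`")
    f1_val <- f1_class[match(positive, classes)]
  } else {
    f1_val <- sum(f1_class * support) / sum(support)
  }
  # multiclass MCC (reduces to the usual formula for two classes)
  s <- sum(cm)
  c_diag <- sum(diag(cm))
  t_k <- rowSums(cm)
  p_k <- colSums(cm)
  num <- c_diag * s - sum(t_k * p_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  mcc <- if (den == 0) 0 else num / den
  structure(list(balanced_accuracy = bal_acc, f1 = unname(f1_val),
                 mcc = mcc),
            class = "training_metrics")
}

#' @export
print.training_metrics <- function(x, ...) {
  cat(sprintf("balanced accuracy %.3f | F1 %.3f | MCC %.3f\n",
              x$balanced_accuracy, x$f1, x$mcc))
  invisible(x)
}

#' Training-set fit metrics
#'
#' Evaluates a model on data with known labels using argmax predictions.
#' In this analysis the models are deliberately evaluated on their own
#' training data: the aim is to describe patterns in the cohort
#' (microscope-AI), not to estimate generalization.
#'
#' @param model A [severity_model()].
#' @param x Feature matrix.
#' @param y True labels: severity levels for multiclass, or either severity
#'   levels or 0/1 indicators for one-vs-rest.
#' @return A `training_metrics` list.
#' @export
evaluate_training_fit <- function(model, x, y) {
  pred <- predict(model, x, type = "class")
  if (model$kind == "one_vs_rest") {
    if (!all(y %in% c(0, 1))) y <- binarize_labels(y, model$target_level)
    classification_metrics(y, pred, f1 = "binary", positive = 1)
  } else {
    classification_metrics(y, pred, f1 = "weighted")
  }
}
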