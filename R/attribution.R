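# parse the fitted ensemble into a plain data.frame (one row per node)
tree_table <- function(model) {
  as.data.frame(xgboost::xgb.model.dt.tree(model = model$booster))
}

#' Shapley feature attributions for a fitted severity model
#'
#' Computes exact per-sample, per-class, per-feature Shapley values of the
#' model margin (log-odds scale) under the interventional expectation over a
#' background set. Because every tree in a [severity_model()] is a
#' single-split stump, the ensemble is additive across features, so the
#' Shapley value of feature j is simply the sum over trees splitting on j of
#' the tree's leaf value at the sample minus its background mean — exact,
#' with local accuracy holding to machine precision. Features no tree splits
#' on receive exactly 0 (null-player property). For one-vs-rest models the
#' negative class is the negation of the positive class.
#'
#' @param model A [severity_model()].
#' @param x Feature matrix of samples to explain.
#' @param background Feature matrix defining the reference distribution;
#'   defaults to the model's training data.
#' @return Object of class `attribution_set`: list with `values` (samples x
#'   classes x features array), `base_values` (per-class expected margin),
#'   `class_labels` and `feature_names`. `values[s, c, ] + base_values[c]`
#'   equals the margin of sample `s` for class `c`.
#' @export
attributions <- function(model, x, background = NULL) {
  x <- check_features(model, x)
  if (is.null(background)) background <- model$training_data
  background <- check_features(model, background)

  ens <- model$ensemble
  v_x <- ensemble_leaf_matrix(model$booster, ens, x)
  vbar <- colMeans(ensemble_leaf_matrix(model$booster, ens, background))

  k <- length(model$class_labels)
  p <- length(model$feature_names)
  n <- nrow(x)
  phi <- array(0, dim = c(n, k, p),
               dimnames = list(rownames(x),
                               as.character(model$class_labels),
                               model$feature_names))
  base_tree <- numeric(ens$n_margin)
  for (t in seq_len(ens$n_tree)) {
    cls <- ens$tree_class[t]
    base_tree[cls] <- base_tree[cls] + vbar[t]
    f <- ens$root_feature[t]
    if (f == "Leaf") next
    j <- match(f, model$feature_names)
    d <- v_x[, t] - vbar[t]
    if (model$kind == "one_vs_rest") {
      phi[, 2, j] <- phi[, 2, j] + d
    } else {
      phi[, cls, j] <- phi[, cls, j] + d
    }
  }
  base <- ens$intercept + base_tree
  if (model$kind == "one_vs_rest") {
    phi[, 1, ] <- -phi[, 2, , drop = FALSE]
    base_values <- c(-base, base)
  } else {
    base_values <- base
  }
  names(base_values) <- as.character(model$class_labels)
  structure(list(values = phi, base_values = base_values,
                 class_labels = model$class_labels,
                 feature_names = model$feature_names),
            class = "attribution_set")
}

#' @export
print.attribution_set <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("attribution_set: %d samples x %d classes x %d features (margin scale)\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Exact Shapley values by subset enumeration
#'
#' The classical Shapley formula evaluated over all 2^p feature coalitions —
#' the brute-force oracle the tree attribution is verified against. The
#' value function maps a coalition (an integer vector of feature indices,
#' possibly empty) to the expected model output with those features fixed.
#'
#' @param value_function Function of one argument, a coalition `S`
#'   (integer vector), returning a scalar `v(S)`.
#' @param n_features Number of features `p`; must be <= 12 (enumeration).
#' @param feature_names Optional names for the result.
#' @return Named numeric vector of Shapley values; their sum equals
#'   `v(1:p) - v(integer(0))` (efficiency).
#' @export
exact_shapley <- function(value_function, n_features, feature_names = NULL) {
  p <- as.integer(n_features)
  if (p > 12)
    stop("subset enumeration is limited to 12 features; ",
         "use attributions() for larger models")
  masks <- 0:(2^p - 1)
  members <- lapply(masks, function(m) which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) > 0))
  v <- vapply(members, function(S) value_function(S), numeric(1))
  sizes <- vapply(members, length, integer(1))
  w <- factorial(0:(p - 1)) * factorial(p - (0:(p - 1)) - 1) / factorial(p)
  phi <- numeric(p)
  for (m in masks) {
    S <- members[[m + 1]]
    s <- sizes[m + 1]
    for (i in seq_len(p)) {
      if (bitwAnd(m, bitwShiftL(1L, i - 1L)) > 0) next
      m_with <- m + bitwShiftL(1L, i - 1L)
      phi[i] <- phi[i] + w[s + 1] * (v[m_with + 1] - v[m + 1])
    }
  }
  names(phi) <- feature_names %||% paste0("f", seq_len(p))
  phi
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Interventional value function of a model margin
#'
#' Builds the coalition value function used by [exact_shapley()]: for a
#' coalition `S`, features in `S` are fixed at the explained sample's values
#' and the rest marginalized over the background rows; the value is the mean
#' class margin.
#'
#' @param model A [severity_model()].
#' @param x_row Single-row feature matrix (the sample to explain).
#' @param background Background feature matrix.
#' @param class_label Class whose margin is attributed.
#' @return Function mapping a coalition to a scalar.
#' @export
model_value_function <- function(model, x_row, background, class_label) {
  x_row <- check_features(model, x_row)
  background <- check_features(model, background)
  ci <- match(class_label, model$class_labels)
  if (is.na(ci)) stop("unknown class label")
  function(S) {
    mat <- background
    if (length(S)) mat[, S] <- rep(x_row[1, S], each = nrow(mat))
    m <- predict(model, mat, type = "margin")
    mean(m[, ci])
  }
}
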