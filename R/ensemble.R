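# Parsed view of a fitted stump ensemble.
#
# Every tree is either a single-split stump or a lone leaf, so the model
# margin decomposes as intercept + sum of per-tree leaf values. Leaf values
# are read off the tree dump once and margins are accumulated in double
# precision; the booster is only consulted to route samples to leaves
# (predleaf), which is exact. The intercept per class is recovered from a
# single float-precision margin comparison and snapped to remove float noise.
build_ensemble <- function(booster, kind, n_class, train_x) {
  tt <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  trees <- sort(unique(tt$Tree))
  n_tree <- length(trees)
  roots <- tt[tt$Node == 0, ]
  roots <- roots[order(roots$Tree), ]
  leaves <- tt[tt$Feature == "Leaf", ]
  lv <- matrix(NA_real_, n_tree, 3)
  lv[cbind(leaves$Tree + 1L, leaves$Node + 1L)] <- leaves$Gain

  n_margin <- if (kind == "multiclass") n_class else 1L
  tree_class <- (trees %% n_margin) + 1L

  ens <- list(n_tree = n_tree, leaf_values = lv,
              root_feature = roots$Feature, tree_class = tree_class,
              n_margin = n_margin)

  # intercept: float margin of one training row minus double leaf sum
  v1 <- ensemble_leaf_matrix(booster, ens,
                             train_x[1, , drop = FALSE])
  m1 <- predict(booster, train_x[1, , drop = FALSE], outputmargin = TRUE)
  m1 <- as.numeric(m1)
  sums <- vapply(seq_len(n_margin), function(cl)
    sum(v1[1, tree_class == cl]), numeric(1))
  ens$intercept <- round(m1 - sums, 4)
  ens
}

# samples x trees matrix of leaf values
ensemble_leaf_matrix <- function(booster, ens, x) {
  idx <- predict(booster, x, predleaf = TRUE)
  if (!is.matrix(idx)) idx <- matrix(idx, nrow = nrow(x))
  out <- matrix(0, nrow(x), ens$n_tree)
  for (t in seq_len(ens$n_tree))
    out[, t] <- ens$leaf_values[t, idx[, t] + 1L]
  out
}

# double-precision per-class margins: intercept + sum of leaf values
ensemble_margins <- function(model, x, leaf_matrix = NULL) {
  ens <- model$ensemble
  v <- leaf_matrix %||% ensemble_leaf_matrix(model$booster, ens, x)
  m <- matrix(0, nrow(v), ens$n_margin)
  for (cl in seq_len(ens$n_margin)) {
    sel <- ens$tree_class == cl
    m[, cl] <- ens$intercept[cl] +
      rowSums(v[, sel, drop = FALSE])
  }
  m
}
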