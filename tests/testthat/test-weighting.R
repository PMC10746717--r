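test_that("predictions are grouped by confidence and correctness", {
  r <- group_predictions(predicted_labels = c(3, 4, 3),
                         predicted_probabilities = c(0.8, 0.7, 0.6),
                         true_labels = c(3, 3, 3))
  expect_equal(r$group, c("Positive", "Negative", "Borderline"))
  # p = 0.6 exactly is borderline even when correct (threshold is strict)
  expect_equal(group_predictions(3, 0.6, 3)$group, "Borderline")
  # without ground truth only confidence is known
  r2 <- group_predictions(c(3, 4), c(0.9, 0.5))
  expect_equal(r2$group, c("Confident", "Borderline"))
  expect_error(group_predictions(c(3, 4), 0.9), "misaligned")
  expect_error(group_predictions(3, 0.9, tau = 0), "tau")
})

test_that("the weighting formulas evaluate exactly and never flip signs", {
  expect_equal(weight_value(0.5, 0.8, "Positive"), 2.5)
  expect_equal(weight_value(0.5, 0.8, "Negative"), 0.1)
  expect_equal(weight_value(-0.3, 0.55, "Borderline"), -0.3)
  # clipping keeps the positive weight finite at p = 1
  expect_true(is.finite(weight_value(1, 1, "Positive")))
  expect_equal(weight_value(1, 1, "Positive"), 1 / 1e-6)

  # monotone in p: amplification grows, shrinkage falls
  p <- seq(0.61, 0.99, by = 0.02)
  expect_true(all(diff(weight_value(1, p, "Positive")) > 0))
  expect_true(all(diff(weight_value(1, p, "Negative")) < 0))

  set.seed(1)
  orig <- rnorm(500)
  p <- runif(500, 0.61, 0.999)
  grp <- sample(c("Positive", "Negative", "Borderline"), 500, TRUE)
  w <- weight_value(orig, p, grp)
  expect_true(all(sign(w) == sign(orig)))
  expect_true(all(abs(w[grp == "Positive"]) >=
                    abs(orig[grp == "Positive"]) / (1 - 0.6)))
  expect_true(all(abs(w[grp == "Negative"]) <=
                    abs(orig[grp == "Negative"]) * (1 - 0.6)))
})

test_that("per-class weighting upweights the true class and downweights the rest", {
  # one multiclass sample, correct and confident: p = (0.05, 0.9, 0.05)
  vals <- array(0.2, dim = c(1, 3, 2))
  a <- manual_attribution_set(vals, class_labels = c(2L, 3L, 4L))
  rec <- group_predictions(3L, 0.9, 3L)
  prob <- matrix(c(0.05, 0.9, 0.05), 1, 3)
  w <- weight_attributions(a, rec, prob, "incl_bl")
  expect_equal(unname(w$values[1, 2, 1]), 0.2 / (1 - 0.9))  # 2.0
  expect_equal(unname(w$values[1, 1, 1]), 0.2 * (1 - 0.05)) # 0.19
  expect_equal(unname(w$values[1, 3, 1]), 0.19)

  # incorrect prediction: the true class is upweighted instead
  rec2 <- group_predictions(4L, 0.7, 3L)
  prob2 <- matrix(c(0.1, 0.2, 0.7), 1, 3)
  w2 <- weight_attributions(a, rec2, prob2, "incl_bl")
  expect_equal(unname(w2$values[1, 2, 1]), 0.2 / (1 - 0.2))
  expect_equal(unname(w2$values[1, 3, 1]), 0.2 * (1 - 0.7))

  # borderline samples pass through unchanged
  rec3 <- group_predictions(3L, 0.5, 3L)
  w3 <- weight_attributions(a, rec3, prob, "incl_bl")
  expect_identical(w3$values[1, , ], a$values[1, , ])

  expect_error(weight_attributions(a, group_predictions(3L, 0.9), prob,
                                   "incl_bl"), "ground-truth")
})

test_that("degenerate thresholds reduce both modes to the unweighted ranking", {
  d <- random_levels_data(n = 50, p = 8, seed = 16)
  m <- severity_model(d$x, d$levels, "multiclass", nrounds = 30, seed = 5)
  a <- attributions(m, d$x)
  prob <- predict(m, d$x, type = "prob")
  cls <- predict(m, d$x, type = "class")
  pmax_ <- prob[cbind(seq_len(nrow(prob)), max.col(prob, "first"))]

  # tau = 1: everything is borderline, incl_bl is the identity
  rec1 <- group_predictions(cls, pmax_, d$levels, tau = 1)
  w1 <- weight_attributions(a, rec1, prob, "incl_bl")
  expect_identical(w1$values, a$values)
  expect_identical(aggregate_importance(w1)$accession,
                   aggregate_importance(a)$accession)

  # no borderline samples: excl_bl keeps everything unchanged
  rec2 <- group_predictions(cls, pmax_, d$levels, tau = 0.01)
  expect_true(all(rec2$group != "Borderline"))
  w2 <- weight_attributions(a, rec2, mode = "excl_bl")
  expect_identical(w2$values, a$values)
  expect_identical(aggregate_importance(w2)$score,
                   aggregate_importance(a)$score)

  # all borderline: excl_bl has nothing left
  rec3 <- group_predictions(cls, pmax_, d$levels, tau = 1)
  expect_error(weight_attributions(a, rec3, mode = "excl_bl"), "retained")
})

test_that("importance aggregation ranks by absolute sum with lexicographic ties", {
  vals <- array(c(2, -3), dim = c(1, 1, 2))
  a <- manual_attribution_set(vals, class_labels = 1L,
                              feature_names = c("A", "B"))
  rk <- aggregate_importance(a)
  expect_equal(rk$accession, c("B", "A"))
  expect_equal(rk$score, c(3, 2))

  # exact ties break lexicographically by accession
  vals2 <- array(c(1, 1, 1), dim = c(1, 1, 3))
  a2 <- manual_attribution_set(vals2, 1L, c("Q9", "A1", "M5"))
  expect_equal(aggregate_importance(a2)$accession, c("A1", "M5", "Q9"))

  # signed aggregation can cancel
  vals3 <- array(c(1, -1, 0.5, 0.4), dim = c(2, 1, 2))
  a3 <- manual_attribution_set(vals3, 1L, c("A", "B"))
  expect_equal(aggregate_importance(a3, signed = TRUE)$accession[1], "B")
  expect_equal(aggregate_importance(a3, signed = FALSE)$accession[1], "A")
  expect_equal(aggregate_importance(a3, signed = TRUE)$score,
               c(abs(0.5 + 0.4), abs(1 - 1)))
})

test_that("ranking comparison flags new top-k entries and rank shifts", {
  mk <- function(acc) {
    structure(data.frame(rank = seq_along(acc), accession = acc,
                         score = rev(seq_along(acc)),
                         stringsAsFactors = FALSE),
              class = c("feature_ranking", "data.frame"), k = 15)
  }
  acc <- sprintf("P%02d", 1:20)
  expect_equal(compare_rankings(mk(acc), mk(acc), 15)$new_in_b, character(0))

  swapped <- acc; swapped[15] <- acc[16]; swapped[16] <- acc[15]
  cmp <- compare_rankings(mk(acc), mk(swapped), 15)
  expect_equal(cmp$new_in_b, "P16")

  # reversed ranking of 15 features: no new entries, shifts 14, 12, ..., 0, ..., 14
  a15 <- mk(acc[1:15]); b15 <- mk(rev(acc[1:15]))
  cmp2 <- compare_rankings(a15, b15, 15)
  expect_equal(cmp2$new_in_b, character(0))
  shifts <- cmp2$shifts[order(cmp2$shifts$rank_b), "shift"]
  expect_equal(abs(shifts), abs(16 - 2 * (15:1)))

  expect_error(compare_rankings(a15, b15, 16), "exceeds")
})
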