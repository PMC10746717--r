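test_that("cohort dimensions and label histogram follow the configuration", {
  cfg <- sim_config(counts_per_level = c("2" = 5, "3" = 15, "4" = 10),
                    n_proteins = 40, contaminant_names = character(0),
                    seed = 3)
  coh <- simulate_cohort(cfg)
  expect_equal(dim(coh$quant$values), c(30, 40))
  expect_equal(unname(table(coh$clinical$mgd_level)),
               table(c(rep(2, 5), rep(3, 15), rep(4, 10))),
               ignore_attr = TRUE)
  v <- coh$quant$values
  expect_true(all(is.na(v) | v == 0 | v > 0))
  # contaminants appear as extra named columns when configured
  cfg2 <- sim_config(counts_per_level = c("2" = 5, "3" = 5), n_proteins = 10,
                     seed = 3)
  coh2 <- simulate_cohort(cfg2)
  expect_equal(ncol(coh2$quant$values), 10 + 5)
  expect_true("Dermcidin" %in% coh2$quant$proteins$name)
})

test_that("identical configuration and seed give bit-identical cohorts", {
  cfg <- sim_config(counts_per_level = c("2" = 8, "4" = 12), n_proteins = 30,
                    planted_effects = list(planted_effect(3, c("4" = 1))),
                    seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(counts_per_level = c("2" = 0, "3" = 5)), "> 0")
  expect_error(sim_config(counts_per_level = c("7" = 5)), "1,2,3,4")
  expect_error(sim_config(inference_zero_rate = 1.5), "0,1")
  expect_error(sim_config(base_abundance = c(meanlog = 10, sdlog = -1)),
               "sdlog")
})

test_that("planted effects shift group means as specified", {
  # empty effect list is the identity
  m <- matrix(rnorm(40), 10, 4)
  lv <- rep(c(2L, 4L), each = 5)
  expect_identical(apply_severity_effects(m, lv, list()), m)
  expect_error(apply_severity_effects(m, lv,
                                      list(planted_effect(9, c("4" = 1)))),
               "unknown protein")

  # a +1 log2 shift at level 4 doubles the level-4 geometric mean
  cfg <- sim_config(counts_per_level = c("2" = 400, "4" = 400),
                    n_proteins = 5, contaminant_names = character(0),
                    planted_effects = list(planted_effect(1, c("4" = 1))),
                    missingness = list(midpoint = -Inf, slope = 1),
                    inference_zero_rate = 0, seed = 5)
  coh <- simulate_cohort(cfg)
  lg <- log2(coh$quant$values[, 1])
  ratio <- 2^(mean(lg[coh$clinical$mgd_level == 4]) -
              mean(lg[coh$clinical$mgd_level == 2]))
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)

  # a monotone specification yields strictly ordered group means
  cfg2 <- sim_config(counts_per_level = c("2" = 150, "3" = 150, "4" = 150),
                     n_proteins = 3, contaminant_names = character(0),
                     planted_effects = list(
                       planted_effect(2, c("2" = 0, "3" = 0.5, "4" = 1))),
                     missingness = list(midpoint = -Inf, slope = 1),
                     inference_zero_rate = 0, seed = 6)
  coh2 <- simulate_cohort(cfg2)
  gm <- tapply(log2(coh2$quant$values[, 2]), coh2$clinical$mgd_level, mean)
  expect_true(gm[["2"]] < gm[["3"]] && gm[["3"]] < gm[["4"]])
})

test_that("missingness follows the logistic detection curve", {
  set.seed(2)
  raw <- matrix(rlnorm(20000, 12, 2), 200, 100)
  # forced detection / non-detection
  expect_false(anyNA(apply_missingness(raw,
                                       list(midpoint = -Inf, slope = 1))))
  expect_true(all(is.na(apply_missingness(raw,
                                          list(midpoint = Inf, slope = 1)))))
  # missing rate decreases with abundance decile
  miss <- apply_missingness(raw, list(midpoint = 12, slope = 1), seed = 4)
  dec <- cut(log(raw), breaks = quantile(log(raw), 0:10 / 10),
             include.lowest = TRUE, labels = FALSE)
  rate <- tapply(as.vector(is.na(miss)), dec, mean)
  expect_true(all(diff(rate) <= 0))
  expect_error(apply_missingness(raw * 0, list(midpoint = 0, slope = 1)),
               "positive")
})
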