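test_that("sparse severity levels are excluded with their patients", {
  v <- matrix(rlnorm(7 * 3, 8, 1), 7, 3,
              dimnames = list(sprintf("S%03d", 1:7), paste0("P", 1:3)))
  quant <- quant_table(v)
  clin <- clinical_table(rownames(v), c(1L, 2L, 2L, 3L, 3L, 4L, 4L))
  out <- exclude_sparse_levels(clin, quant, min_count = 2)
  expect_equal(sort(unique(out$clinical$mgd_level)), c(2L, 3L, 4L))
  expect_false("S001" %in% out$clinical$sample_id)
  expect_equal(rownames(out$quant$values), out$clinical$sample_id)

  # identity when every level is large enough
  out2 <- exclude_sparse_levels(out$clinical, out$quant, min_count = 2)
  expect_identical(out2$clinical, out$clinical)
  expect_identical(out2$quant$values, out$quant$values)

  expect_error(exclude_sparse_levels(clin, quant, min_count = 10),
               "degenerate")
})

test_that("contaminant filtering removes by name with a keep list", {
  nms <- c("Keratin, type I cytoskeletal 18",
           "Keratin, type II cytoskeletal 1", "Dermcidin", "Lysozyme C")
  v <- matrix(1, 2, 4, dimnames = list(NULL, paste0("A", 1:4)))
  q <- quant_table(v, data.frame(accession = paste0("A", 1:4), name = nms))
  kept <- filter_contaminants(q)$proteins$name
  expect_equal(kept, c("Keratin, type I cytoskeletal 18", "Lysozyme C"))

  trp <- c("Trypsin-1", "Putative trypsin-6")
  q2 <- quant_table(matrix(1, 2, 2, dimnames = list(NULL, c("B1", "B2"))),
                    data.frame(accession = c("B1", "B2"), name = trp))
  expect_equal(ncol(filter_contaminants(q2)$values), 0)

  q3 <- quant_table(matrix(1, 2, 2, dimnames = list(NULL, c("C1", "C2"))),
                    data.frame(accession = c("C1", "C2"),
                               name = c("Lactotransferrin", "Lipocalin-1")))
  expect_identical(filter_contaminants(q3)$values, q3$values)
})

test_that("never-detected proteins are dropped, sparse ones kept", {
  v <- matrix(rlnorm(9), 3, 3, dimnames = list(NULL, c("P1", "P2", "P3")))
  v[, 2] <- NA
  v[2:3, 3] <- NA   # one detected value out of three: kept
  q <- drop_undetected(quant_table(v))
  expect_equal(colnames(q$values), c("P1", "P3"))
  expect_identical(drop_undetected(q)$values, q$values)
})

test_that("special values encode as 0 -> 1 first, then missing -> 0", {
  v <- matrix(c(0, NA, 5.2, 3), 2, 2,
              dimnames = list(NULL, c("P1", "P2")))
  enc <- encode_special_values(quant_table(v))$values
  expect_equal(enc[1, 1], 1)    # inference zero
  expect_equal(enc[2, 1], 0)    # not detected
  expect_equal(enc[1, 2], 5.2)  # ordinary value unchanged
})

test_that("log-standardization centres and scales with stored parameters", {
  set.seed(1)
  v <- matrix(rlnorm(60, 6, 1), 12, 5,
              dimnames = list(NULL, paste0("P", 1:5)))
  v[, 4] <- 7   # constant feature
  v[1, 5] <- 0  # log1p(0) = 0 before scaling
  q <- quant_table(v)
  pm <- log_standardize(q)
  s <- pm$values
  nonconst <- c(1, 2, 3, 5)
  expect_lt(max(abs(colMeans(s[, nonconst]))), 1e-8)
  sd_pop <- apply(s[, nonconst], 2, function(c) sqrt(mean((c - mean(c))^2)))
  expect_lt(max(abs(sd_pop - 1)), 1e-8)
  expect_true(all(s[, 4] == 0))
  expect_equal(unname(pm$transform_params$sd[4]), 0)
  expect_equal(log1p(0), 0)

  # stored parameters reproduce the training encoding bit for bit
  expect_identical(apply_log_standardize(q, pm$transform_params), s)

  vneg <- v; vneg[1, 1] <- -1
  expect_error(quant_table(vneg), "negative")
})

test_that("composed preprocessing equals stepwise application", {
  cfg <- sim_config(counts_per_level = c("1" = 1, "2" = 6, "3" = 10,
                                         "4" = 8),
                    n_proteins = 25, seed = 9)
  coh <- simulate_cohort(cfg)
  prep <- preprocess_quant(coh$quant, coh$clinical)

  s1 <- exclude_sparse_levels(coh$clinical, coh$quant)
  s2 <- filter_contaminants(s1$quant)
  s3 <- drop_undetected(s2)
  s4 <- encode_special_values(s3)
  s5 <- log_standardize(s4)
  expect_identical(prep$matrix$values, s5$values)

  # the lone level-1 patient is excluded; columns never increase
  expect_false(1L %in% prep$clinical$mgd_level)
  expect_true(ncol(s2$values) <= ncol(s1$quant$values))
  expect_true(ncol(s3$values) <= ncol(s2$values))
  expect_equal(ncol(s4$values), ncol(s3$values))
  # keratin 18 survives the contaminant filter, the others do not
  expect_true("P05783" %in% prep$encoded$proteins$accession)
  expect_false(any(c("P04264", "P81605", "P07477", "Q8NHM4") %in%
                     prep$encoded$proteins$accession))
})
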