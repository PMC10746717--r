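# shared fixtures, all built in code

# feature matrix whose class is decided by a threshold on the first feature
separable_data <- function(n = 40, p = 2, frac_pos = 0.5, gap = 1,
                           seed = 1) {
  set.seed(seed)
  n_pos <- round(n * frac_pos)
  y <- c(rep(0L, n - n_pos), rep(1L, n_pos))
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  x[, 1] <- ifelse(y == 1, abs(rnorm(n)) + gap, -abs(rnorm(n)) - gap)
  list(x = x, y = y)
}

random_levels_data <- function(n = 60, p = 6, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  lv <- sample(2:4, n, replace = TRUE)
  # make levels learnable from the first two features
  x[, 1] <- x[, 1] + (lv - 3)
  x[, 2] <- x[, 2] - (lv - 3)
  list(x = x, levels = lv)
}

# 10 x 8 quantification table exercising every preprocessing rule:
# keratin 1 / dermcidin / trypsin-1 are contaminants, keratin 18 is the
# keep-list probe, one column is entirely missing, one entry is a recorded
# 0 (protein inference) and one is missing (not detected)
preprocess_fixture <- function() {
  nms <- c("Keratin, type II cytoskeletal 1",
           "Keratin, type I cytoskeletal 18",
           "Dermcidin",
           "Trypsin-1",
           "Lysozyme C",
           "Never detected protein",
           "Protein with inference zero",
           "Protein with a missing value")
  accs <- c("P04264", "P05783", "P81605", "P07477", "P61626",
            "X00001", "X00002", "X00003")
  set.seed(7)
  v <- matrix(round(stats::rlnorm(80, 8, 1), 2), 10, 8,
              dimnames = list(sprintf("S%03d", 1:10), accs))
  v[, 6] <- NA          # never detected
  v[3, 7] <- 0          # protein inference
  v[5, 8] <- NA         # single non-detection
  quant_table(v, data.frame(accession = accs, name = nms,
                            stringsAsFactors = FALSE))
}

# hand-built attribution set (2 samples x 2 classes x 2 features)
manual_attribution_set <- function(values, class_labels = c(0L, 1L),
                                   feature_names = NULL) {
  d <- dim(values)
  feature_names <- feature_names %||% paste0("f", seq_len(d[3]))
  dimnames(values) <- list(sprintf("S%03d", seq_len(d[1])),
                           as.character(class_labels), feature_names)
  structure(list(values = values,
                 base_values = stats::setNames(numeric(d[2]),
                                               as.character(class_labels)),
                 class_labels = class_labels,
                 feature_names = feature_names),
            class = "attribution_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
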