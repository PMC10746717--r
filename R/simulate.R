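#' Simulation configuration for a synthetic tear-proteome cohort
#'
#' Describes a cohort of patients graded by meibomian gland dysfunction
#' (MGD) severity together with a label-free protein quantification matrix.
#' The defaults reproduce the structure of the clinical cohort the analysis
#' is designed for: 31/126/76 patients at severity levels 2/3/4, about two
#' thousand protein features with right-skewed (log-normal) peak areas,
#' abundance-dependent non-detection, occasional protein-inference zeros,
#' and named contaminant proteins (keratins, dermcidin, trypsins) so the
#' preprocessing filters are exercised.
#'
#' @param counts_per_level Named integer vector: severity level -> number of
#'   patients. Names are levels in 1..4.
#' @param n_proteins Number of non-contaminant protein features.
#' @param planted_effects List of [planted_effect()] objects describing
#'   severity-dependent abundance shifts.
#' @param missingness List with `midpoint` and `slope` of the logistic
#'   detection curve on the natural-log abundance scale: the probability
#'   that an entry with raw value `x` is detected is
#'   `plogis(slope * (log(x) - midpoint))`. Use `midpoint = -Inf`
#'   (with positive slope) to force full detection and `midpoint = Inf` to
#'   force complete non-detection.
#' @param contaminant_names Character vector of contaminant protein names to
#'   inject as extra columns.
#' @param inference_zero_rate Probability that a detected value is recorded
#'   as 0 (protein inference).
#' @param base_abundance Named vector `c(meanlog=, sdlog=)` of the log-normal
#'   distribution of per-protein baseline abundances (natural-log scale).
#' @param noise_sdlog Within-protein between-sample standard deviation on
#'   the natural-log scale.
#' @param seed Integer seed; all randomness in [simulate_cohort()] derives
#'   from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(counts_per_level = c("2" = 31, "3" = 126, "4" = 76),
                       n_proteins = 2000,
                       planted_effects = list(),
                       missingness = list(midpoint = 9, slope = 0.8),
                       contaminant_names = default_contaminant_names(),
                       inference_zero_rate = 0.01,
                       base_abundance = c(meanlog = 12, sdlog = 2),
                       noise_sdlog = 0.5,
                       seed = 1L) {
  if (is.null(names(counts_per_level)))
    stop("`counts_per_level` must be named by severity level")
  lv <- as.integer(names(counts_per_level))
  if (!all(lv %in% 1:4)) stop("severity levels must lie in {1,2,3,4}")
  if (any(counts_per_level <= 0)) stop("all patient counts must be > 0")
  if (n_proteins <= 0) stop("`n_proteins` must be > 0")
  if (inference_zero_rate < 0 || inference_zero_rate > 1)
    stop("`inference_zero_rate` must lie in [0,1]")
  if (base_abundance[["sdlog"]] <= 0) stop("`sdlog` must be > 0")
  if (noise_sdlog <= 0) stop("`noise_sdlog` must be > 0")
  if (!all(c("midpoint", "slope") %in% names(missingness)))
    stop("`missingness` needs `midpoint` and `slope`")
  for (e in planted_effects) {
    if (!inherits(e, "planted_effect"))
      stop("`planted_effects` must be a list of planted_effect objects")
  }
  structure(list(counts_per_level = counts_per_level,
                 n_proteins = as.integer(n_proteins),
                 planted_effects = planted_effects,
                 missingness = missingness,
                 contaminant_names = contaminant_names,
                 inference_zero_rate = inference_zero_rate,
                 base_abundance = base_abundance,
                 noise_sdlog = noise_sdlog,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default injected contaminant proteins
#'
#' Keratins, dermcidin and trypsins are the classic skin / digestion-reagent
#' contaminants of tear proteomics. Keratin 18 is included deliberately as a
#' keep-list probe: the contaminant filter must retain it.
#'
#' @return Named character vector, accession -> protein name.
#' @export
default_contaminant_names <- function() {
  c("P04264" = "Keratin, type II cytoskeletal 1",
    "P05783" = "Keratin, type I cytoskeletal 18",
    "P81605" = "Dermcidin",
    "P07477" = "Trypsin-1",
    "Q8NHM4" = "Putative trypsin-6")
}

#' Planted severity effect
#'
#' A protein whose mean log2 abundance is shifted by severity level,
#' emulating a true severity biomarker.
#'
#' @param protein Feature identifier: integer column index or accession.
#' @param log2_fc_per_level Named numeric vector: severity level -> log2
#'   shift relative to the cohort baseline. Levels not listed shift by 0,
#'   so the baseline level is any level omitted from (or set to 0 in) the map.
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(protein, log2_fc_per_level) {
  if (is.null(names(log2_fc_per_level)))
    stop("`log2_fc_per_level` must be named by severity level")
  lv <- as.integer(names(log2_fc_per_level))
  if (!all(lv %in% 1:4)) stop("severity levels must lie in {1,2,3,4}")
  if (!all(is.finite(log2_fc_per_level))) stop("shifts must be finite")
  structure(list(protein = protein, log2_fc_per_level = log2_fc_per_level),
            class = "planted_effect")
}

# deterministic sub-seed derivation so every stage has its own stream
derive_seed <- function(seed, k) {
  (as.double(seed) * 1103515245 + 12345 * k) %% 2147483647
}

with_seed <- function(seed, expr) {
  set.seed(as.integer(seed))
  expr
}

#' Simulate a synthetic cohort
#'
#' Generates a protein quantification table and matching clinical severity
#' labels under the configured model: per-protein log-normal baselines,
#' within-protein Gaussian noise on the log scale, planted severity effects,
#' abundance-dependent (missing-not-at-random) non-detection and
#' protein-inference zeros. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with elements `quant` ([quant_table()]) and `clinical`
#'   ([clinical_table()]).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop("`config` must be a sim_config")
  counts <- config$counts_per_level
  levels <- as.integer(names(counts))
  ord <- order(levels)
  labels <- rep(levels[ord], counts[ord])
  n <- length(labels)
  clinical <- clinical_table(sprintf("S%03d", seq_len(n)), labels)

  n_syn <- config$n_proteins
  cont <- config$contaminant_names
  accs <- c(sprintf("SYN%04d", seq_len(n_syn)), names(cont))
  nms <- c(sprintf("Synthetic protein %d", seq_len(n_syn)), unname(cont))
  p <- length(accs)

  meanlog <- config$base_abundance[["meanlog"]]
  sdlog <- config$base_abundance[["sdlog"]]
  base <- with_seed(derive_seed(config$seed, 1),
                    stats::rnorm(p, meanlog, sdlog))
  noise <- with_seed(derive_seed(config$seed, 2),
                     matrix(stats::rnorm(n * p, 0, config$noise_sdlog), n, p))
  log2mat <- sweep(noise, 2, base, "+") / log(2)  # to log2 scale
  dimnames(log2mat) <- list(clinical$sample_id, accs)

  log2mat <- apply_severity_effects(log2mat, clinical,
                                    config$planted_effects)
  raw <- 2^log2mat
  raw <- apply_missingness(raw, config$missingness,
                           seed = derive_seed(config$seed, 3))
  if (config$inference_zero_rate > 0) {
    u <- with_seed(derive_seed(config$seed, 4),
                   matrix(stats::runif(n * p), n, p))
    raw[!is.na(raw) & u < config$inference_zero_rate] <- 0
  }
  proteins <- data.frame(accession = accs, name = nms,
                         stringsAsFactors = FALSE)
  list(quant = quant_table(raw, proteins), clinical = clinical)
}

#' Shift group means of planted proteins
#'
#' Adds severity-level-specific log2 shifts to selected columns of a log2
#' abundance matrix (applied before missingness is imposed).
#'
#' @param log2_matrix Samples x proteins matrix on the log2 scale.
#' @param labels A [clinical_table()] or an integer vector of severity
#'   levels aligned with the matrix rows.
#' @param effects List of [planted_effect()] objects.
#' @return The shifted matrix.
#' @export
apply_severity_effects <- function(log2_matrix, labels, effects) {
  lv <- if (inherits(labels, "clinical_table")) labels$mgd_level else labels
  if (length(lv) != nrow(log2_matrix))
    stop("labels do not align with matrix rows")
  for (e in effects) {
    j <- e$protein
    if (is.character(j)) j <- match(j, colnames(log2_matrix))
    if (is.na(j) || j < 1 || j > ncol(log2_matrix))
      stop("planted effect references an unknown protein")
    for (s in names(e$log2_fc_per_level)) {
      rows <- lv == as.integer(s)
      log2_matrix[rows, j] <- log2_matrix[rows, j] + e$log2_fc_per_level[[s]]
    }
  }
  log2_matrix
}

#' Impose abundance-dependent non-detection
#'
#' Each entry of a strictly positive raw-scale matrix is independently set
#' to `NA` (not detected) with probability `1 - detect`, where
#' `detect = plogis(slope * (log(x) - midpoint))` increases with abundance —
#' the standard missing-not-at-random detection-limit mechanism of label-free
#' LC-MS.
#'
#' @param raw_matrix Strictly positive numeric matrix (raw peak areas).
#' @param spec List with `midpoint` and `slope` (see [sim_config()]).
#' @param seed Integer seed.
#' @return The matrix with `NA` in non-detected cells.
#' @export
apply_missingness <- function(raw_matrix, spec, seed = 1L) {
  if (any(raw_matrix <= 0, na.rm = TRUE))
    stop("`raw_matrix` must be strictly positive")
  z <- spec$slope * (log(raw_matrix) - spec$midpoint)
  detect <- stats::plogis(z)
  u <- with_seed(seed, matrix(stats::runif(length(raw_matrix)),
                              nrow(raw_matrix), ncol(raw_matrix)))
  raw_matrix[u >= detect] <- NA
  raw_matrix
}
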