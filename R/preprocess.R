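#' Contaminant filtering rules
#'
#' Tear samples collected on Schirmer strips carry skin proteins (keratins,
#' dermcidins/dermacolins) and the digestion reagent trypsin. All of these
#' are removed by case-insensitive substring match on the protein NAME,
#' except keratins 18 and 19, which are genuine tear-film constituents and
#' are protected by the keep patterns (keep wins over remove).
#'
#' @param remove_name_patterns Character vector of lower-case substrings
#'   marking contaminants.
#' @param keep_name_patterns Character vector of lower-case substrings that
#'   override removal.
#' @return List of class `contaminant_rules`.
#' @export
contaminant_rules <- function(remove_name_patterns = c("keratin", "dermcidin",
                                                       "dermacolin",
                                                       "dermcoline",
                                                       "trypsin"),
                              keep_name_patterns =
                                c("keratin, type i cytoskeletal 18",
                                  "keratin, type i cytoskeletal 19")) {
  if (length(remove_name_patterns) == 0 ||
      any(!nzchar(remove_name_patterns)))
    stop("remove patterns must be non-empty strings")
  if (any(!nzchar(keep_name_patterns)))
    stop("keep patterns must be non-empty strings")
  structure(list(remove_name_patterns = tolower(remove_name_patterns),
                 keep_name_patterns = tolower(keep_name_patterns)),
            class = "contaminant_rules")
}

matches_any <- function(x, patterns) {
  hit <- rep(FALSE, length(x))
  for (p in patterns) hit <- hit | grepl(p, x, fixed = TRUE)
  hit
}

#' Remove severity levels with too few patients
#'
#' Severity grades represented by fewer than `min_count` patients cannot
#' support group-wise modelling and are dropped from both the clinical table
#' and the quantification table (the cohort here contained a single level-1
#' patient, who was excluded).
#'
#' @param clinical A [clinical_table()].
#' @param quant A [quant_table()] sharing `clinical$sample_id`.
#' @param min_count Minimum number of patients a level needs to be kept.
#' @return List with filtered `clinical` and `quant`, rows in original order.
#' @export
exclude_sparse_levels <- function(clinical, quant, min_count = 2) {
  if (!identical(clinical$sample_id, rownames(quant$values)))
    stop("clinical and quantification tables do not share sample ids")
  tab <- table(clinical$mgd_level)
  keep_levels <- as.integer(names(tab)[tab >= min_count])
  keep <- clinical$mgd_level %in% keep_levels
  if (!any(keep))
    stop("no severity level has at least ", min_count,
         " patients: degenerate cohort")
  list(clinical = clinical_table(clinical$sample_id[keep],
                                 clinical$mgd_level[keep]),
       quant = select_samples(quant, keep))
}

#' Drop contaminant protein columns
#'
#' @param quant A [quant_table()].
#' @param rules A [contaminant_rules()].
#' @return Filtered [quant_table()], column order preserved.
#' @export
filter_contaminants <- function(quant, rules = contaminant_rules()) {
  nm <- tolower(quant$proteins$name)
  drop <- matches_any(nm, rules$remove_name_patterns) &
    !matches_any(nm, rules$keep_name_patterns)
  select_proteins(quant, !drop)
}

#' Drop proteins never detected in any sample
#'
#' An all-missing column carries no information; any column with at least
#' one detected (or inference) value is kept.
#'
#' @param quant A [quant_table()].
#' @return Filtered [quant_table()].
#' @export
drop_undetected <- function(quant) {
  keep <- colSums(!is.na(quant$values)) > 0
  select_proteins(quant, keep)
}

#' Encode the two special quantification states
#'
#' Recorded zeros mark protein inference and become 1; only then are
#' not-detected (`NA`) entries set to 0 (peak area of an undetected protein).
#' The order of the two rewrites is mandatory — reversing it would merge the
#' two states.
#'
#' @param quant A [quant_table()].
#' @return A [quant_table()] with no missing entries.
#' @export
encode_special_values <- function(quant) {
  v <- quant$values
  if (any(v < 0, na.rm = TRUE)) stop("negative peak areas are invalid")
  v[!is.na(v) & v == 0] <- 1   # protein inference
  v[is.na(v)] <- 0             # not detected
  quant_table(v, quant$proteins)
}

#' Log-transform and standardize a fully encoded table
#'
#' Applies `log1p` (natural log of 1 + x, so an undetected 0 maps to 0 and
#' the transform is defined everywhere), then centres and scales each
#' feature with its population mean and standard deviation. Constant
#' features map to all-zero columns with a recorded sd of 0.
#'
#' @param quant A [quant_table()] with no missing entries (run
#'   [encode_special_values()] first).
#' @return An object of class `preprocessed_matrix`: list with `values`
#'   (standardized samples x features matrix) and `transform_params`
#'   (per-feature `mean` and `sd` on the log scale, reusable via
#'   [apply_log_standardize()]).
#' @export
log_standardize <- function(quant) {
  v <- quant$values
  if (anyNA(v)) stop("missing entries present: run encode_special_values()")
  if (any(v < 0)) stop("negative values are invalid")
  l <- log1p(v)
  mu <- colMeans(l)
  sd_pop <- sqrt(colMeans(sweep(l, 2, mu)^2))
  params <- list(mean = mu, sd = sd_pop)
  structure(list(values = standardize_log(l, params),
                 transform_params = params,
                 proteins = quant$proteins),
            class = "preprocessed_matrix")
}

standardize_log <- function(l, params) {
  scale_safe <- ifelse(params$sd > 0, params$sd, 1)
  out <- sweep(sweep(l, 2, params$mean), 2, scale_safe, "/")
  out[, params$sd == 0] <- 0
  out
}

#' Re-apply stored transform parameters to new raw data
#'
#' @param quant A [quant_table()] with no missing entries, with the same
#'   feature columns used when the parameters were fitted.
#' @param transform_params The `transform_params` of a fitted
#'   [log_standardize()].
#' @return Standardized numeric matrix.
#' @export
apply_log_standardize <- function(quant, transform_params) {
  v <- quant$values
  if (anyNA(v) || any(v < 0)) stop("encode special values first")
  if (!identical(colnames(v), names(transform_params$mean)))
    stop("feature columns do not match the stored transform")
  standardize_log(log1p(v), transform_params)
}

#' @export
print.preprocessed_matrix <- function(x, ...) {
  cat(sprintf("preprocessed_matrix: %d samples x %d features (log1p + standard scaling)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Run the full preprocessing pipeline
#'
#' Applies, in this fixed order: sparse-level exclusion, contaminant
#' removal, removal of never-detected proteins, special-value encoding,
#' log transform + standardization.
#'
#' @inheritParams exclude_sparse_levels
#' @param rules A [contaminant_rules()].
#' @return List with `matrix` (the [log_standardize()] output), `encoded`
#'   (the encoded [quant_table()], the raw-scale input of the
#'   differential-abundance stage), `clinical` (filtered labels) and
#'   `report` (per-stage column/row counts and removed accessions).
#' @export
preprocess_quant <- function(quant, clinical, rules = contaminant_rules(),
                             min_count = 2) {
  st1 <- exclude_sparse_levels(clinical, quant, min_count)
  st2 <- filter_contaminants(st1$quant, rules)
  st3 <- drop_undetected(st2)
  st4 <- encode_special_values(st3)
  mat <- log_standardize(st4)
  report <- list(
    n_samples_in = nrow(quant$values),
    n_samples_kept = nrow(st4$values),
    excluded_samples = setdiff(clinical$sample_id, st1$clinical$sample_id),
    n_proteins_in = ncol(quant$values),
    contaminants_removed = setdiff(st1$quant$proteins$accession,
                                   st2$proteins$accession),
    undetected_removed = setdiff(st2$proteins$accession,
                                 st3$proteins$accession),
    n_proteins_kept = ncol(st4$values))
  list(matrix = mat, encoded = st4, clinical = st1$clinical, report = report)
}
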