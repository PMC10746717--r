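#' Protein quantification table
#'
#' Container for a samples x proteins matrix of relative protein
#' quantifications (label-free peak areas, arbitrary units). Two special
#' states are preserved: `NA` means the protein was not detected in that
#' sample, and `0` marks a protein-inference quantification (a measurement
#' that cannot be unambiguously assigned to the protein).
#'
#' @param values Numeric matrix, samples in rows, proteins in columns.
#'   Row names are sample identifiers, column names are protein accessions.
#'   Entries are `NA` (not detected), `0` (protein inference) or positive
#'   peak areas.
#' @param proteins Optional data frame with columns `accession` and `name`
#'   giving protein metadata in column order. Defaults to using the
#'   accessions as names.
#' @return An object of class `quant_table` with elements `values` and
#'   `proteins`.
#' @export
quant_table <- function(values, proteins = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x proteins)")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("P%04d", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("sample identifiers must be unique")
  if (anyDuplicated(colnames(values)))
    stop("protein accessions must be unique")
  if (any(values < 0, na.rm = TRUE))
    stop("peak areas cannot be negative")
  if (any(!is.finite(values) & !is.na(values)))
    stop("peak areas must be finite or NA")
  if (is.null(proteins)) {
    proteins <- data.frame(accession = colnames(values),
                           name = colnames(values),
                           stringsAsFactors = FALSE)
  }
  if (!all(c("accession", "name") %in% names(proteins)))
    stop("`proteins` needs columns `accession` and `name`")
  # a zero-column matrix normalizes its column names to NULL
  if (!identical(as.character(proteins$accession),
                 colnames(values) %||% character(0)))
    stop("`proteins$accession` must match the matrix column names in order")
  structure(list(values = values, proteins = proteins), class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  v <- x$values
  cat(sprintf("quant_table: %d samples x %d proteins\n", nrow(v), ncol(v)))
  cat(sprintf("  not detected (NA): %d entries; inference zeros: %d entries\n",
              sum(is.na(v)), sum(v == 0, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.quant_table <- function(x) dim(x$values)

# keep a subset of protein columns, preserving order
select_proteins <- function(quant, keep) {
  v <- quant$values[, keep, drop = FALSE]
  # 0-column subsets lose their dimnames; restore them
  dimnames(v) <- list(rownames(quant$values), colnames(quant$values)[keep])
  pr <- quant$proteins[keep, , drop = FALSE]
  rownames(pr) <- NULL
  quant_table(v, pr)
}

select_samples <- function(quant, keep) {
  quant_table(quant$values[keep, , drop = FALSE], quant$proteins)
}

#' Clinical severity table
#'
#' @param sample_id Character vector of sample identifiers.
#' @param mgd_level Integer severity grades, each in 1..4.
#' @return Data frame of class `clinical_table`.
#' @export
clinical_table <- function(sample_id, mgd_level) {
  sample_id <- as.character(sample_id)
  mgd_level <- as.integer(mgd_level)
  if (length(sample_id) != length(mgd_level))
    stop("`sample_id` and `mgd_level` must have the same length")
  if (anyDuplicated(sample_id)) stop("sample identifiers must be unique")
  if (!all(mgd_level %in% 1:4)) stop("severity levels must lie in {1,2,3,4}")
  structure(data.frame(sample_id = sample_id, mgd_level = mgd_level,
                       stringsAsFactors = FALSE),
            class = c("clinical_table", "data.frame"))
}

#' Read / write quantification and clinical tables as TSV
#'
#' The quantification TSV has one row per sample: a `sample_id` column
#' followed by one column per protein accession; empty cells are
#' not-detected entries. Protein name metadata travels in a companion
#' two-column TSV (`accession`, `name`).
#'
#' @param quant A [quant_table()].
#' @param file Path of the quantification TSV.
#' @param proteins_file Optional path of the protein metadata TSV.
#' @return `write_quant_tsv` returns `file` invisibly; `read_quant_tsv`
#'   returns a [quant_table()].
#' @export
write_quant_tsv <- function(quant, file, proteins_file = NULL) {
  df <- data.frame(sample_id = rownames(quant$values),
                   quant$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  if (!is.null(proteins_file))
    utils::write.table(quant$proteins, proteins_file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_quant_tsv
#' @export
read_quant_tsv <- function(file, proteins_file = NULL) {
  df <- utils::read.delim(file, check.names = FALSE, na.strings = "",
                          stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- df$sample_id
  proteins <- NULL
  if (!is.null(proteins_file))
    proteins <- utils::read.delim(proteins_file, stringsAsFactors = FALSE)
  quant_table(values, proteins)
}

#' @param clinical A [clinical_table()].
#' @rdname write_quant_tsv
#' @export
write_clinical_tsv <- function(clinical, file) {
  utils::write.table(clinical, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_quant_tsv
#' @export
read_clinical_tsv <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  clinical_table(df$sample_id, df$mgd_level)
}
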