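#' Pipeline run configuration
#'
#' Exactly one input mode must be given: a [sim_config()] for a synthetic
#' cohort, or paths to quantification / clinical TSV files.
#'
#' @param sim A [sim_config()], or NULL when reading files.
#' @param quant_file,clinical_file,proteins_file Input TSV paths (see
#'   [read_quant_tsv()]); used when `sim` is NULL.
#' @param output_dir Directory the run writes into (created if needed).
#' @param tau Confidence threshold for prediction grouping.
#' @param top_k Ranking report cutoff.
#' @param q_max,fc_min Differential-abundance thresholds.
#' @param nrounds Boosting rounds per model.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = NULL, quant_file = NULL, clinical_file = NULL,
                       proteins_file = NULL, output_dir,
                       tau = 0.6, top_k = 15, q_max = 0.01, fc_min = 2,
                       nrounds = 100, seed = 1L) {
  if (is.null(sim) == is.null(quant_file))
    stop("give exactly one of `sim` or `quant_file`/`clinical_file`")
  if (!is.null(quant_file) && is.null(clinical_file))
    stop("`clinical_file` is required with `quant_file`")
  if (top_k < 1) stop("`top_k` must be >= 1")
  structure(list(sim = sim, quant_file = quant_file,
                 clinical_file = clinical_file,
                 proteins_file = proteins_file,
                 output_dir = output_dir, tau = tau, top_k = top_k,
                 q_max = q_max, fc_min = fc_min, nrounds = nrounds,
                 seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage `%s` failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

write_ranking_tsv <- function(ranking, proteins, file, top_k,
                              flag_new = character(0)) {
  top <- utils::head(ranking, top_k)
  out <- data.frame(rank = top$rank,
                    accession = top$accession,
                    name = proteins$name[match(top$accession,
                                               proteins$accession)],
                    score = top$score,
                    flag_new = top$accession %in% flag_new,
                    stringsAsFactors = FALSE)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}

#' Run the full analysis end to end
#'
#' Executes preprocessing, the four classifiers (one multiclass over the
#' severity levels present plus one one-vs-rest model per level), training
#' metrics, Shapley attributions, unweighted and uncertainty-weighted
#' feature rankings (both aggregation modes), rank comparisons, and the
#' differential-abundance table. Every stage writes plain-text files under
#' `config$output_dir`, and a JSON manifest records each file with its MD5
#' checksum together with all analysis parameters, so a run is verifiably
#' deterministic given its seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the manifest, metrics, rankings,
#'   comparisons and the differential-abundance table.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("`config` must be a run_config")
  out <- config$output_dir
  for (d in c("", "input", "models", "metrics", "rankings", "comparisons",
              "differential"))
    dir.create(file.path(out, d), showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  add_file <- function(path) files <<- c(files, path)

  dat <- stage("input", {
    if (!is.null(config$sim)) {
      cohort <- simulate_cohort(config$sim)
      write_quant_tsv(cohort$quant, file.path(out, "input", "quant.tsv"),
                      file.path(out, "input", "proteins.tsv"))
      write_clinical_tsv(cohort$clinical,
                         file.path(out, "input", "clinical.tsv"))
      add_file("input/quant.tsv"); add_file("input/proteins.tsv")
      add_file("input/clinical.tsv")
      cohort
    } else {
      list(quant = read_quant_tsv(config$quant_file, config$proteins_file),
           clinical = read_clinical_tsv(config$clinical_file))
    }
  })

  prep <- stage("preprocess", preprocess_quant(dat$quant, dat$clinical))
  jsonlite::write_json(prep$report,
                       file.path(out, "preprocess_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  add_file("preprocess_report.json")

  levels_present <- sort(unique(prep$clinical$mgd_level))
  tasks <- c(list(list(name = "multiclass", kind = "multiclass",
                       target = NULL)),
             lapply(levels_present, function(l)
               list(name = sprintf("ovr_level%d", l), kind = "one_vs_rest",
                    target = l)))

  x <- prep$matrix$values
  y <- prep$clinical$mgd_level
  proteins <- prep$encoded$proteins
  metrics_rows <- list()
  rankings <- list()
  comparisons <- list()

  for (i in seq_along(tasks)) {
    tk <- tasks[[i]]
    model <- stage(paste0("train:", tk$name),
                   severity_model(x, y, kind = tk$kind,
                                  target_level = tk$target,
                                  nrounds = config$nrounds,
                                  seed = derive_seed(config$seed, 10 + i)))
    dump_file <- file.path("models", paste0(tk$name, "_trees.txt"))
    writeLines(xgboost::xgb.dump(model$booster), file.path(out, dump_file))
    add_file(dump_file)
    meta_file <- file.path("models", paste0(tk$name, "_meta.json"))
    jsonlite::write_json(list(kind = tk$kind, target_level = tk$target,
                              class_labels = model$class_labels,
                              nrounds = model$nrounds,
                              seed = model$seed),
                         file.path(out, meta_file), auto_unbox = TRUE,
                         pretty = TRUE)
    add_file(meta_file)

    m <- stage(paste0("metrics:", tk$name),
               evaluate_training_fit(model, x, y))
    metrics_rows[[tk$name]] <- m
    mfile <- file.path("metrics", paste0(tk$name, "_metrics.json"))
    jsonlite::write_json(unclass(m), file.path(out, mfile),
                         auto_unbox = TRUE, pretty = TRUE)
    add_file(mfile)

    expl <- stage(paste0("explain:", tk$name), {
      attr <- attributions(model, x)
      prob <- predict(model, x, type = "prob")
      cls <- predict(model, x, type = "class")
      truth <- if (tk$kind == "multiclass") y
               else binarize_labels(y, tk$target)
      recs <- group_predictions(cls, prob[cbind(seq_len(nrow(prob)),
                                                max.col(prob, "first"))],
                                true_labels = truth, tau = config$tau,
                                sample_ids = prep$clinical$sample_id)
      list(attr = attr, prob = prob, recs = recs)
    })

    rk <- stage(paste0("rank:", tk$name), {
      unweighted <- aggregate_importance(expl$attr, k = config$top_k)
      incl <- aggregate_importance(
        weight_attributions(expl$attr, expl$recs, expl$prob, "incl_bl"),
        k = config$top_k)
      excl <- aggregate_importance(
        weight_attributions(expl$attr, expl$recs, mode = "excl_bl"),
        k = config$top_k)
      list(unweighted = unweighted, incl_bl = incl, excl_bl = excl)
    })
    rankings[[tk$name]] <- rk

    cmp_incl <- compare_rankings(rk$unweighted, rk$incl_bl, config$top_k)
    cmp_excl <- compare_rankings(rk$unweighted, rk$excl_bl, config$top_k)
    comparisons[[tk$name]] <- list(incl_bl = cmp_incl, excl_bl = cmp_excl)

    for (mode in names(rk)) {
      rfile <- file.path("rankings", sprintf("%s_%s.tsv", tk$name, mode))
      flag <- switch(mode, unweighted = character(0),
                     incl_bl = cmp_incl$new_in_b,
                     excl_bl = cmp_excl$new_in_b)
      write_ranking_tsv(rk[[mode]], proteins, file.path(out, rfile),
                        config$top_k, flag)
      add_file(rfile)
    }
    cfile <- file.path("comparisons", paste0(tk$name, "_comparisons.json"))
    jsonlite::write_json(
      list(incl_bl = list(new_in_top_k = cmp_incl$new_in_b,
                          shifts = cmp_incl$shifts),
           excl_bl = list(new_in_top_k = cmp_excl$new_in_b,
                          shifts = cmp_excl$shifts)),
      file.path(out, cfile), auto_unbox = TRUE, pretty = TRUE)
    add_file(cfile)
  }

  mt <- data.frame(model = names(metrics_rows),
                   balanced_accuracy = vapply(metrics_rows,
                                              `[[`, 0, "balanced_accuracy"),
                   f1 = vapply(metrics_rows, `[[`, 0, "f1"),
                   mcc = vapply(metrics_rows, `[[`, 0, "mcc"))
  utils::write.table(mt, file.path(out, "metrics", "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  add_file("metrics/metrics.tsv")

  diff <- stage("differential",
                differential_abundance(prep$encoded, prep$clinical,
                                       q_max = config$q_max,
                                       fc_min = config$fc_min))
  dfile <- "differential/differential_abundance.tsv"
  utils::write.table(diff, file.path(out, dfile), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  add_file(dfile)

  manifest <- list(
    parameters = list(tau = config$tau, eps = 1e-6, top_k = config$top_k,
                      q_max = config$q_max, fc_min = config$fc_min,
                      nrounds = config$nrounds, seed = config$seed,
                      aggregation = "absolute sum",
                      log_transform = "log1p (natural)"),
    files = lapply(sort(files), function(f)
      list(path = f, md5 = unname(tools::md5sum(file.path(out, f))))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(manifest = manifest, metrics = mt, rankings = rankings,
                 comparisons = comparisons, differential = diff))
}
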