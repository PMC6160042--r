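# Pipeline orchestration: assemble the configured input (a measured run,
# run subtraction, the run-mean ensemble or the per-run probability
# ensemble), apply the wavelet stage, run cross-validation with in-fold
# selection, and summarise ROC performance per classifier.

#' Pipeline configuration
#'
#' The defaults mirror the recommended pipeline: run 2 data, a 2D discrete
#' wavelet transform, `sigma = 0`, filter selection with `nKeep = 2`, no
#' PCA, and all five classifiers.
#'
#' @param run Input selector: `"run1"`, `"run2"`, `"run3"`,
#'   `"subtract13"` (run 1 minus run 3), `"subtract31"`, `"run_mean"`
#'   (average of the three runs) or `"prob_ensemble"` (classify each run
#'   separately, then average the probabilities).
#' @param wavelet A [wavelet_spec()].
#' @param selection A [selection_spec()].
#' @param cv A [cv_spec()].
#' @param models Named list of [model_spec()]s.
#' @param demographics `"off"` (wavelet features only), `"only"` (the four
#'   demographic covariates are the whole feature set, bypassing
#'   selection), or `"combined"` (demographics appended to the in-fold
#'   selected wavelet features).
#' @param n_boot Bootstrap replicates for the ROC summaries.
#' @param out_dir Optional output directory; when given, predictions,
#'   metrics, ROC points, selected features and a reproducibility manifest
#'   are written there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(run = "run2", wavelet = wavelet_spec(),
                            selection = selection_spec(), cv = cv_spec(),
                            models = default_models(),
                            demographics = c("off", "only", "combined"),
                            n_boot = 2000L, out_dir = NULL) {
  run_opts <- c("run1", "run2", "run3", "subtract13", "subtract31",
                "run_mean", "prob_ensemble")
  if (!run %in% run_opts) {
    stop("run must be one of: ", paste(run_opts, collapse = ", "))
  }
  demographics <- match.arg(demographics)
  structure(list(run = run, wavelet = wavelet, selection = selection,
                 cv = cv, models = models, demographics = demographics,
                 n_boot = as.integer(n_boot), out_dir = out_dir),
            class = "pipeline_config")
}

# Demographics as a numeric feature table (sex encoded 0/1 for M).
.demographics_table <- function(samples) {
  m <- cbind(sex = as.numeric(samples$sex == "M"), age = samples$age,
             alcohol = samples$alcohol, bmi = samples$bmi)
  rownames(m) <- samples$sample_id
  feature_table(m, "demographics")
}

# Input feature tables for the configured run selector: a list of one raw
# table, or three for the probability ensemble.
.assemble_inputs <- function(runs, config) {
  sel <- config$run
  if (sel %in% c("run1", "run2", "run3")) {
    list(build_table(runs, as.integer(substring(sel, 4L))))
  } else if (sel == "subtract13") {
    list(combine_subtract(build_table(runs, 1L), build_table(runs, 3L)))
  } else if (sel == "subtract31") {
    list(combine_subtract(build_table(runs, 3L), build_table(runs, 1L)))
  } else if (sel == "run_mean") {
    list(combine_mean(lapply(1:3, function(r) build_table(runs, r))))
  } else {
    lapply(1:3, function(r) build_table(runs, r))
  }
}

#' Run the full classification pipeline
#'
#' Executes input assembly, the wavelet stage, cross-validation with
#' in-fold selection, and ROC summarisation for every configured
#' classifier.  With `demographics = "only"` the four demographic
#' covariates form the entire (unselected) feature set; with `"combined"`
#' they are appended to the in-fold selected wavelet features.
#'
#' @param config A [pipeline_config()].
#' @param cohort List with `runs` (list of [faims_run()]s) and `samples`
#'   (metadata data frame), e.g. from [generate_cohort()] or
#'   [read_cohort()].
#' @return List with `predictions` (per-model [prediction_set()]s),
#'   `metrics` (per-model [roc_summary()]s), `selection` (per-fold selected
#'   features), and `manifest`.  Output files are written when
#'   `config$out_dir` is set.
#' @export
run_pipeline <- function(config, cohort) {
  stopifnot(inherits(config, "pipeline_config"))
  samples <- cohort$samples
  labels <- as_class_labels(samples$label)
  demo <- .demographics_table(samples)
  if (config$demographics == "only") {
    sel <- config$selection
    sel$method <- "embedded"  # all four covariates go straight in
    preds <- cross_validate(demo, labels, config$models, sel, config$cv)
  } else {
    message("assembling input tables (", config$run, ")")
    tables <- .assemble_inputs(cohort$runs, config)
    message("wavelet stage (", config$wavelet$mode, ")")
    tables <- lapply(tables, wavelet_table, spec = config$wavelet)
    extra <- if (config$demographics == "combined") demo else NULL
    per_table <- lapply(seq_along(tables), function(i) {
      message("cross-validation on input table ", i, "/", length(tables))
      cross_validate(tables[[i]], labels, config$models, config$selection,
                     config$cv, always_include = extra)
    })
    preds <- if (length(per_table) == 1L) {
      per_table[[1L]]
    } else {
      out <- lapply(names(config$models), function(m) {
        probability_ensemble(lapply(per_table, `[[`, m))
      })
      names(out) <- names(config$models)
      attr(out, "selection") <- do.call(rbind, lapply(seq_along(per_table),
        function(i) cbind(input = i, attr(per_table[[i]], "selection"))))
      out
    }
  }
  metrics <- lapply(preds, roc_summary, n_boot = config$n_boot,
                    seed = config$cv$seed)
  manifest <- list(
    package = "faimspipe",
    version = as.character(utils::packageVersion("faimspipe")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = .serialise_config(config))
  result <- list(predictions = preds, metrics = metrics,
                 selection = attr(preds, "selection"), manifest = manifest,
                 config = config)
  if (!is.null(config$out_dir)) .write_outputs(result, config$out_dir)
  result
}

.serialise_config <- function(config) {
  list(run = config$run,
       wavelet = unclass(config$wavelet),
       selection = unclass(config$selection),
       cv = unclass(config$cv),
       models = lapply(config$models, unclass),
       demographics = config$demographics,
       n_boot = config$n_boot)
}

.write_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  preds <- do.call(rbind, lapply(names(result$predictions), function(m) {
    ps <- result$predictions[[m]]
    data.frame(sample_id = ps$sample_id, model = m, fold = ps$fold,
               probability = ps$probability, label = as.character(ps$label))
  }))
  utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  metrics <- lapply(result$metrics, function(s) {
    list(auc = s$auc, auc_ci = s$auc_ci, threshold = s$threshold,
         sensitivity = s$sensitivity, sensitivity_ci = s$sensitivity_ci,
         specificity = s$specificity, specificity_ci = s$specificity_ci,
         n_boot = s$n_boot, seed = s$seed)
  })
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (m in names(result$predictions)) {
    ps <- result$predictions[[m]]
    rp <- roc_points(ps$label, ps$probability)
    utils::write.table(rp, file.path(out_dir, paste0("roc_", m, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(result$selection)) {
    utils::write.table(result$selection,
                       file.path(out_dir, "selected_features.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read a cohort from disk
#'
#' Loads every run file (`*.txt`, the package dialect) in a directory plus
#' the accompanying metadata CSV.
#'
#' @param data_dir Directory of run files written by [write_faims_run()] /
#'   [write_cohort()].
#' @param metadata Path to the metadata CSV (default
#'   `file.path(data_dir, "metadata.csv")`).
#' @return List with `runs` and `samples`, as accepted by [run_pipeline()].
#' @export
read_cohort <- function(data_dir,
                        metadata = file.path(data_dir, "metadata.csv")) {
  files <- sort(list.files(data_dir, pattern = "\\.txt$", full.names = TRUE))
  if (length(files) == 0L) stop("no run files (*.txt) in ", data_dir)
  list(runs = lapply(files, read_faims_run),
       samples = read_sample_metadata(metadata))
}

#' Write a cohort to disk
#'
#' One run file per sample and run in the package's text dialect, plus
#' `metadata.csv`.
#'
#' @param cohort List with `runs` and `samples`.
#' @param data_dir Output directory (created if needed).
#' @return `data_dir`, invisibly.
#' @export
write_cohort <- function(cohort, data_dir) {
  dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
  for (run in cohort$runs) {
    write_faims_run(run, file.path(data_dir, sprintf("%s_run%d.txt",
                                                     run$sample_id,
                                                     run$run_index)))
  }
  utils::write.csv(cohort$samples, file.path(data_dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(data_dir)
}

#' Build a pipeline configuration from a YAML file
#'
#' Recognised blocks: `run`, `wavelet.*` (`mode`, `crop_rows`,
#' `crop_offset`, `vanishing_moments`), `select.*` (`sigma`, `nkeep`,
#' `method`, `pca`, `pca_var`, `wrapper_start`), `cv.*` (`k`, `seed`,
#' `stratified`), `models` (list of kinds), `demographics`, `n_boot`,
#' `out_dir`, and an optional `synth.*` block passed to [synth_spec()].
#'
#' @param path YAML file path.
#' @return List with `config` (a [pipeline_config()]) and `synth` (a
#'   [synth_spec()] or NULL).
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  grab <- function(block, fn) {
    if (is.null(block)) fn() else do.call(fn, block)
  }
  models <- if (is.null(y$models)) {
    default_models()
  } else {
    stats::setNames(lapply(y$models, model_spec), unlist(y$models))
  }
  sel <- y$select
  selection <- selection_spec(
    sigma = sel$sigma %||% 0, nkeep = sel$nkeep %||% 2L,
    method = sel$method %||% "filter", use_pca = isTRUE(sel$pca),
    pca_var_threshold = sel$pca_var %||% 0.95,
    wrapper_n_start = sel$wrapper_start %||% 5L)
  config <- pipeline_config(
    run = y$run %||% "run2",
    wavelet = grab(y$wavelet, wavelet_spec),
    selection = selection,
    cv = grab(y$cv, cv_spec),
    models = models,
    demographics = y$demographics %||% "off",
    n_boot = y$n_boot %||% 2000L,
    out_dir = y$out_dir)
  synth <- if (is.null(y$synth)) NULL else do.call(synth_spec, y$synth)
  list(config = config, synth = synth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
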