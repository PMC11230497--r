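# End-to-end workflow: simulate/load -> omega -> graphs -> split/augment ->
# train -> predict -> metrics/BAG -> group statistics -> importance ->
# optional exposome and quality stages. Deterministic given the config and
# its seeds; every run serializes its configuration next to the outputs.

#' Pipeline configuration
#'
#' Validates and fixes every option of [run_pipeline()]. Following the
#' training protocol, the age model is fit on healthy controls only (80/20
#' age-stratified split with augmentation on the training side); clinical
#' groups are scored with the trained model and compared via BAG statistics.
#'
#' @param cohort A [cohort_config()] for the synthetic stage, or `NULL` when
#'   `input_dir` points at fixtures written by [write_fixture_set()].
#' @param input_dir Optional fixture directory (must contain `cohort.tsv` and
#'   per-subject `*_timeseries.tsv` files).
#' @param output_dir Where reports are written; created if missing.
#' @param train_fraction,n_age_bins Split options (defaults 0.8, 5).
#' @param n_augment Augmented training graphs (default 500).
#' @param plan A [training_plan()].
#' @param n_permutation_iterations Iterations per group permutation test
#'   (default 5000).
#' @param n_importance_bootstrap Bootstrap resamples for node importance
#'   (default 5000).
#' @param run_importance,run_exposome,run_quality Stage switches.
#' @param seed Master seed for stages without their own.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            input_dir = NULL,
                            output_dir = tempfile("brainclock_run_"),
                            train_fraction = 0.8,
                            n_age_bins = 5,
                            n_augment = 500,
                            plan = training_plan(),
                            n_permutation_iterations = 5000,
                            n_importance_bootstrap = 5000,
                            run_importance = TRUE,
                            run_exposome = FALSE,
                            run_quality = FALSE,
                            seed = 1L) {
  if (is.null(cohort) && is.null(input_dir)) {
    stop_brainclock("either a cohort config or an input directory is required",
                    class = "brainclock_config_error")
  }
  if (!is.null(cohort)) stopifnot(inherits(cohort, "cohort_config"))
  stopifnot(inherits(plan, "training_plan"))
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_brainclock("train_fraction must be in (0, 1)",
                    class = "brainclock_config_error")
  }
  structure(
    list(cohort = cohort, input_dir = input_dir, output_dir = output_dir,
         train_fraction = train_fraction, n_age_bins = as.integer(n_age_bins),
         n_augment = as.integer(n_augment), plan = plan,
         n_permutation_iterations = as.integer(n_permutation_iterations),
         n_importance_bootstrap = as.integer(n_importance_bootstrap),
         run_importance = isTRUE(run_importance),
         run_exposome = isTRUE(run_exposome),
         run_quality = isTRUE(run_quality),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

serialize_config <- function(config, path) {
  ser <- config
  ser$plan <- unclass(ser$plan)
  if (!is.null(ser$cohort)) ser$cohort <- unclass(ser$cohort)
  jsonlite::write_json(unclass(ser), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(path))
}

load_input_graphs <- function(config) {
  if (!is.null(config$input_dir)) {
    if (!dir.exists(config$input_dir)) {
      stop_brainclock("input directory not found: '%s'", config$input_dir,
                      class = "brainclock_io_error")
    }
    cohort <- read_tsv_table(file.path(config$input_dir, "cohort.tsv"))
    ts_list <- lapply(seq_len(nrow(cohort)), function(k) {
      read_timeseries_matrix(
        file.path(config$input_dir,
                  paste0(cohort$subject_id[k], "_timeseries.tsv")),
        modality = cohort$modality[k] %||% "fMRI",
        tr = if (!is.null(config$cohort)) config$cohort$tr else 2
      )
    })
  } else {
    cohort <- generate_cohort_table(config$cohort)
    ts_list <- lapply(seq_len(nrow(cohort)), function(k) {
      simulate_subject_timeseries(cohort[k, ], config$cohort)
    })
  }
  list(cohort = cohort, ts_list = ts_list)
}

#' Run the full brain-age pipeline
#'
#' Executes (optional) simulation, O-information estimation with
#' normalization, graph building and filtering, HC-only stratified
#' train/test split with age-interpolation augmentation, grid-search GCN
#' training, prediction of all subjects, fit metrics and BAGs, subsample
#' permutation tests between diagnostic groups and regions, ablation
#' importance, and optional exposome and quality stages. All artifacts are
#' written under `config$output_dir` (tables as TSV, summary and manifest as
#' structured text).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a `pipeline_result` list: `cohort`, `predictions`
#'   (with BAG), `metrics` (HC holdout), `group_tests`, `importance`,
#'   `model`, `split_sizes`, `config_hash`, `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE, showWarnings = FALSE)) {
    stop_brainclock("cannot create output directory '%s'", out,
                    class = "brainclock_io_error")
  }
  config_hash <- serialize_config(config, file.path(out, "config.json"))

  message("stage: input (simulate or load)")
  inp <- load_input_graphs(config)
  cohort <- inp$cohort

  message(sprintf("stage: omega (%d subjects)", nrow(cohort)))
  graphs <- lapply(seq_len(nrow(cohort)), function(k) {
    m <- normalize_omega(omega_matrix(inp$ts_list[[k]]))
    build_graph(m, cohort[k, ])
  })
  graphs <- filter_invalid(graphs)
  if (!length(graphs)) {
    stop_brainclock("no valid graphs after filtering", class = "brainclock_input_error")
  }

  diag_of <- vapply(graphs, function(g) g$meta$diagnosis %||% "HC", character(1))
  hc <- graphs[diag_of == "HC"]
  patients <- graphs[diag_of != "HC"]
  if (length(hc) < 10) {
    stop_brainclock("need at least 10 healthy-control graphs to train, got %d",
                    length(hc), class = "brainclock_input_error")
  }

  message(sprintf("stage: split (%d HC) + augment (%d)", length(hc), config$n_augment))
  split <- stratified_split(hc, config$train_fraction, config$n_age_bins,
                            seed = child_seed(config$seed, 11L))
  aug <- if (config$n_augment > 0) {
    augment_by_interpolation(split$train, config$n_augment,
                             seed = child_seed(config$seed, 12L))
  } else {
    list()
  }
  split$train <- c(split$train, aug)

  message(sprintf("stage: train (grid of %d x %d)",
                  length(config$plan$learning_rate_grid),
                  length(config$plan$epoch_grid)))
  model <- train_with_grid_search(split, config$plan)

  message("stage: predict + metrics")
  test_preds <- predict_batch(split$test, model)
  metrics <- compute_fit_metrics(test_preds)
  all_scored <- c(split$test, patients)
  preds <- compute_bag(predict_batch(all_scored, model))
  meta <- do.call(rbind, lapply(all_scored, function(g) {
    data.frame(subject_id = g$subject_id,
               diagnosis = g$meta$diagnosis %||% NA_character_,
               sex = g$meta$sex %||% NA_character_,
               region = g$meta$region %||% NA_character_,
               scanner = g$meta$scanner %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  preds <- merge(preds, meta, by = "subject_id", sort = FALSE)

  message("stage: group statistics")
  group_tests <- list()
  for (grp in intersect(c("MCI", "AD", "bvFTD"), unique(preds$diagnosis))) {
    group_tests[[paste0("HC_vs_", grp)]] <- permutation_group_test(
      preds$bag[preds$diagnosis == grp], preds$bag[preds$diagnosis == "HC"],
      n_iterations = config$n_permutation_iterations,
      seed = child_seed(config$seed, 21L)
    )
  }
  if (all(c("LAC", "nonLAC") %in% preds$region)) {
    group_tests[["LAC_vs_nonLAC"]] <- permutation_group_test(
      preds$bag[preds$region == "LAC"], preds$bag[preds$region == "nonLAC"],
      n_iterations = config$n_permutation_iterations,
      seed = child_seed(config$seed, 22L)
    )
  }

  importance <- NULL
  if (config$run_importance) {
    message("stage: importance")
    importance <- bootstrap_importance_table(
      model, split$test, unit_kind = "node",
      n_bootstrap = config$n_importance_bootstrap,
      seed = child_seed(config$seed, 31L)
    )
  }

  exposome_fit <- NULL
  if (config$run_exposome) {
    message("stage: exposome")
    expo <- generate_exposome_table(unique(cohort$country),
                                    seed = child_seed(config$seed, 41L))
    sub <- cohort[match(preds$subject_id, cohort$subject_id), ]
    design <- suppressWarnings(exposome_design(sub, expo, preds$bag))
    exposome_fit <- fit_bag_regression(design, seed = child_seed(config$seed, 42L))
  }

  quality <- NULL
  if (config$run_quality) {
    message("stage: quality")
    qfun <- if ((cohort$modality[1] %||% "fMRI") == "fMRI") fmri_odq else eeg_odq
    quality <- data.frame(
      subject_id = cohort$subject_id,
      odq = vapply(inp$ts_list, function(x) qfun(x)$odq, numeric(1))
    )
  }

  result <- structure(
    list(cohort = cohort, predictions = preds, metrics = metrics,
         group_tests = group_tests, importance = importance,
         exposome = exposome_fit, quality = quality, model = model,
         split_sizes = c(train = length(split$train) - length(aug),
                         augmented = length(aug), test = length(split$test)),
         config_hash = config_hash, output_dir = out),
    class = "pipeline_result"
  )
  write_report(result, out)
  invisible(result)
}

#' Write the pipeline report bundle
#'
#' Emits `predictions.tsv`, `group_tests.tsv`, `importance.tsv` (when
#' computed), `quality.tsv` (when computed), a `summary.txt` with all scalar
#' metrics (fixed 6-significant-digit rendering, stated in the header), and a
#' `manifest.txt` of artifact checksums. Re-rendering the same results is
#' byte-identical.
#'
#' @param results A `pipeline_result` (or a compatible list).
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE, showWarnings = FALSE)) {
    stop_brainclock("cannot create report directory '%s'", path,
                    class = "brainclock_io_error")
  }
  files <- character(0)
  if (!is.null(results$predictions)) {
    write_tsv_table(results$predictions, file.path(path, "predictions.tsv"))
    files <- c(files, "predictions.tsv")
  }
  if (length(results$group_tests %||% list())) {
    gt <- do.call(rbind, lapply(names(results$group_tests), function(nm) {
      x <- results$group_tests[[nm]]
      data.frame(comparison = nm, observed_diff = x$observed_diff,
                 p_two_sided = x$p_two_sided, n_iterations = x$n_iterations,
                 subsample_size = x$subsample_size, seed = x$seed)
    }))
    write_tsv_table(gt, file.path(path, "group_tests.tsv"))
    files <- c(files, "group_tests.tsv")
  }
  if (!is.null(results$importance)) {
    write_tsv_table(as.data.frame(results$importance),
                    file.path(path, "importance.tsv"))
    files <- c(files, "importance.tsv")
  }
  if (!is.null(results$quality)) {
    write_tsv_table(results$quality, file.path(path, "quality.tsv"))
    files <- c(files, "quality.tsv")
  }
  lines <- c(
    "brainclock pipeline summary (numbers rendered with 6 significant digits)",
    sprintf("config_hash: %s", results$config_hash %||% "NA")
  )
  if (!is.null(results$metrics)) {
    m <- results$metrics
    lines <- c(lines, sprintf(
      "holdout: n=%d rmse=%.6g r2=%.6g pearson_r=%.6g cohens_f2=%.6g mde=%.6g",
      m$n, m$rmse, m$r2, m$pearson_r, m$cohens_f2, m$mde))
  }
  if (!is.null(results$split_sizes)) {
    lines <- c(lines, paste0("split: ", paste(names(results$split_sizes),
                                              results$split_sizes,
                                              sep = "=", collapse = " ")))
  }
  if (!is.null(results$model)) {
    lines <- c(lines, sprintf("best_hyperparams: lr=%.6g epochs=%d",
                              results$model$best_hyperparams$lr,
                              results$model$best_hyperparams$epochs))
  }
  writeLines(lines, file.path(path, "summary.txt"))
  files <- c(files, "summary.txt")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(path, files))),
    stringsAsFactors = FALSE
  )
  write_tsv_table(manifest, file.path(path, "manifest.txt"))
  invisible(path)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$metrics)
  cat(sprintf("  %d predictions, %d group tests, outputs in %s\n",
              nrow(x$predictions), length(x$group_tests), x$output_dir))
  invisible(x)
}
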