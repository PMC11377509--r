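## fixed per-stage seed offsets: stages are reproducible in isolation
## from the single run seed
.stage_seed_offsets <- c(simulate = 101L, features = 211L,
                         analysis = 307L, evaluation = 401L)

#' Build a pipeline run configuration
#'
#' @param mode One of `"synthetic_benchmark"` (simulate voltammograms,
#'   extract features, rank and select them, benchmark the four
#'   classifier families on tumor presence and grade),
#'   `"clinical_table3"` (rank-correlation analysis and descriptive
#'   summary of the packaged cohort), `"features_only"` (feature
#'   extraction over a manifest CSV of trace files) or `"calibrate"`
#'   (dose-response fit of a calibration panel CSV).
#' @param seed Single integer seed; each stage derives its own seed
#'   from it by a fixed offset.
#' @param out_dir Output directory (created if missing).
#' @param params Named list of per-mode knobs: `n_per_class`,
#'   `importance_threshold` for the benchmark; `manifest` path for
#'   `features_only`; `panel` path and `electrode_area` for
#'   `calibrate`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic_benchmark", "clinical_table3",
                                "features_only", "calibrate"),
                       seed = 1, out_dir = tempfile("voltsense_run_"),
                       params = list()) {
  if (is.character(mode) && length(mode) == 1 &&
      !mode %in% eval(formals(run_config)$mode))
    stop("invalid mode '", mode, "'; allowed: ",
         paste(eval(formals(run_config)$mode), collapse = ", "),
         call. = FALSE)
  mode <- match.arg(mode)
  structure(list(mode = mode, seed = as.integer(seed), out_dir = out_dir,
                 params = params),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' The format is chosen by file extension (`.yaml`/`.yml` or `.json`).
#' Recognised top-level keys: `mode`, `seed`, `out_dir`, `params`.
#'
#' @param path Configuration file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format '.", ext, "' (use yaml or json)",
         call. = FALSE))
  run_config(mode = raw$mode %||% "synthetic_benchmark",
             seed = raw$seed %||% 1,
             out_dir = raw$out_dir %||% tempfile("voltsense_run_"),
             params = raw$params %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_seed <- function(config, stage) {
  config$seed + .stage_seed_offsets[[stage]]
}

#' Run the analysis pipeline
#'
#' Executes the stage sequence of the configured mode and writes all
#' tables plus a `manifest.json` recording the configuration, package
#' version, per-stage seeds and an md5 checksum of every file written.
#' Two runs with identical configuration produce identical outputs.
#' On a stage failure, partial outputs are kept next to a `FAILED`
#' marker naming the stage, and the error is re-thrown.
#'
#' @param config A [run_config()].
#' @param dry_run Validate the configuration and return the planned
#'   stages without computing.
#' @return The output directory, invisibly (or the stage plan for a
#'   dry run).
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stages <- switch(config$mode,
    synthetic_benchmark = c("simulate", "features", "analysis", "evaluation"),
    clinical_table3 = "analysis",
    features_only = "features",
    calibrate = "analysis")
  if (dry_run) return(stages)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit_csv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }
  emit_json <- function(x, name) {
    p <- file.path(config$out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <<- c(outputs, p)
    p
  }
  current_stage <- stages[1]
  log_stage <- function(stage, msg) {
    current_stage <<- stage
    message(sprintf("[%s] %s", stage, msg))
  }
  tryCatch({
    switch(config$mode,
      clinical_table3 = {
        log_stage("analysis", "clinical rank-correlation analysis")
        cohort <- load_packaged_cohort()
        emit_csv(correlation_table(cohort), "correlation_table.csv")
        s <- cohort_summary(cohort)
        emit_json(list(
          n = s$n, age_mean = s$age_mean, age_sd = s$age_sd,
          age_median = s$age_median, weight_mean = s$weight_mean,
          weight_sd = s$weight_sd, lobe_counts = as.list(s$lobe_counts),
          grade_counts = as.list(stats::setNames(as.integer(s$grade_counts),
                                                 names(s$grade_counts))),
          siln_positive = s$siln_positive, muc1_stained = s$muc1_stained),
          "cohort_summary.json")
      },
      features_only = {
        log_stage("features", "feature extraction over manifest")
        manifest <- config$params$manifest
        if (is.null(manifest)) stop("features_only requires params$manifest")
        mf <- utils::read.csv(manifest, stringsAsFactors = FALSE)
        vgs <- lapply(mf$path, read_voltammogram)
        fm <- extract_feature_matrix(vgs, labels = mf$label)
        emit_csv(fm, "feature_matrix.csv")
      },
      calibrate = {
        log_stage("analysis", "calibration fit")
        panel <- config$params$panel
        if (is.null(panel)) stop("calibrate requires params$panel")
        df <- utils::read.csv(panel, stringsAsFactors = FALSE)
        fit <- fit_calibration(df$concentration, df$response,
                               electrode_area =
                                 config$params$electrode_area %||% 2)
        emit_json(fit[c("slope", "intercept", "r_squared",
                        "sensitivity_per_area", "lod")], "calibration.json")
      },
      synthetic_benchmark = {
        n_per_class <- config$params$n_per_class %||% 15
        log_stage("simulate", sprintf("%d traces per class", n_per_class))
        ds <- simulate_labeled_dataset(grade_class_specs(), n_per_class,
                                       seed = stage_seed(config, "simulate"))
        log_stage("features", "extracting 14 descriptors per trace")
        fm <- extract_feature_matrix(ds$voltammograms, labels = ds$labels)
        emit_csv(fm, "feature_matrix.csv")
        log_stage("analysis", "feature ranking and selection")
        tumor <- fm$label != "control"
        grade_num <- as.integer(factor(fm$label[tumor],
                                       levels = c("grade_I", "grade_II",
                                                  "grade_III")))
        feats <- fm[cv_feature_names()]
        emit_csv(feature_target_correlations(feats[tumor, ], grade_num),
                 "feature_correlations.csv")
        imp <- rf_importance(feats[tumor, ], grade_num,
                             seed = stage_seed(config, "analysis"))
        emit_csv(imp, "feature_importance.csv")
        thr <- config$params$importance_threshold %||% 0.08
        emit_json(list(threshold = thr,
                       selected = select_features(imp, thr)),
                  "selected_features.json")
        log_stage("evaluation", "LOOCV benchmark, presence and grade")
        specs <- default_model_specs(seed = stage_seed(config, "evaluation"))
        presence <- factor(ifelse(tumor, "tumor", "control"))
        rep_presence <- benchmark_models(feats, presence, specs,
                                         positive = "tumor")
        emit_csv(as.data.frame(rep_presence), "benchmark_presence.csv")
        rep_grade <- benchmark_models(feats[tumor, ], grade_num, specs)
        emit_csv(as.data.frame(rep_grade), "benchmark_grade.csv")
      })
    manifest <- list(
      package = "voltsense",
      version = as.character(utils::packageVersion("voltsense")),
      mode = config$mode, seed = config$seed,
      stage_seeds = as.list(vapply(names(.stage_seed_offsets),
                                   function(s) stage_seed(config, s),
                                   numeric(1))),
      params = config$params,
      outputs = lapply(outputs, function(p)
        list(file = basename(p), md5 = unname(tools::md5sum(p)))))
    p <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(config$out_dir)
  }, error = function(e) {
    writeLines(sprintf("stage: %s\nerror: %s", current_stage,
                       conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop(e)
  })
}
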