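#' Load and validate a pipeline configuration
#'
#' A single YAML file drives both workflows. Recognised fields:
#' `peaks` (one or more peak-list CSVs), `metadata`, `design`,
#' `factors` (design worksheet and factor-level CSVs), `output_dir`,
#' `noise_threshold` (200), `ppm_tol` (15), `rt_tol_min` (0.15),
#' `cv_threshold_pct` (20), `qc_drift_threshold` (0.01),
#' `model` (`variant`, `method`, prior scales, `iter`, `burn`), `seed`.
#' Thresholds default to the conventional values shown in parentheses.
#'
#' @param path YAML config path, or a list with the same fields.
#' @return A validated `pipeline_config` list with defaults filled in.
#' @export
load_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) {
      stop(sprintf("config file not found: %s", path), call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    path
  }
  defaults <- list(noise_threshold = 200, ppm_tol = 15, rt_tol_min = 0.15,
                   cv_threshold_pct = 20, qc_drift_threshold = 0.01,
                   output_dir = "pbmetab_out", seed = 1L, model = list())
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  with(cfg, stopifnot(noise_threshold >= 0, ppm_tol > 0, rt_tol_min > 0,
                      cv_threshold_pct >= 0, qc_drift_threshold > 0))
  cfg$source_path <- if (is.character(path)) path else NA_character_
  class(cfg) <- "pipeline_config"
  cfg
}

.provenance <- function(cfg, seed) {
  list(package = "pbmetab",
       version = as.character(utils::packageVersion("pbmetab")),
       config_md5 = if (!is.na(cfg$source_path))
         unname(tools::md5sum(cfg$source_path)) else NA,
       seed = seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

.preprocess <- function(cfg) {
  pls <- read_peak_lists(cfg$peaks, cfg$metadata)
  pls <- lapply(pls, noise_filter, threshold = cfg$noise_threshold)
  align_features(pls, ppm_tol = cfg$ppm_tol, rt_tol_min = cfg$rt_tol_min)
}

#' Run the extraction-method comparison workflow
#'
#' read -> noise filter -> align -> blank filter -> all-replicate presence
#' -> CV classification -> per-method summaries and exclusive intersection
#' counts. Reports are written to the configured output directory
#' (`comparison_summary.{json,csv}`, `intersections.csv`, one
#' `filter_report_<method>.json` per method, `provenance.json`).
#'
#' @param config Path to a YAML config or a config list
#'   (see [load_pipeline_config()]).
#' @return Invisibly, a list with `summary` (`comparison_summary`),
#'   `intersections` (`intersection_counts`) and `table` (the aligned
#'   `feature_table`).
#' @export
run_comparison <- function(config) {
  cfg <- load_pipeline_config(config)
  table <- .preprocess(cfg)
  summary <- summarize_methods(table, cv_threshold_pct = cfg$cv_threshold_pct)
  counts <- intersection_counts(summary$feature_sets)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_comparison(summary, counts,
                   json_path = file.path(out, "comparison_summary.json"),
                   csv_path = file.path(out, "comparison_summary.csv"))
  utils::write.csv(as.data.frame(counts),
                   file.path(out, "intersections.csv"), row.names = FALSE)
  for (m in names(summary$reports)) {
    write_filter_report(summary$reports[[m]],
                        json_path = file.path(out, sprintf(
                          "filter_report_%s.json", m)))
  }
  jsonlite::write_json(.provenance(cfg, cfg$seed),
                       file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(summary = summary, intersections = counts, table = table))
}

#' Run the robustness-testing workflow
#'
#' Validates the Plackett-Burman design (aborting, with the validation
#' report written, if balance or orthogonality fails), preprocesses the
#' peak lists, removes blank features, checks QC drift, assembles the
#' log-abundance dataset and fits the configured model(s). Writes
#' `effect_estimates.{csv,json}`, `qc_drift.json`,
#' `design_validation.json` and `provenance.json`.
#'
#' @param config Path to a YAML config or a config list. Must name `design`
#'   and `factors` CSVs.
#' @return Invisibly, a list with `estimates` (`effect_estimates`),
#'   `qc_drift` (`qc_drift_report` or `NULL` when no QC samples),
#'   `validation` (`design_validation_report`) and `dataset`.
#' @export
run_robustness <- function(config) {
  cfg <- load_pipeline_config(config)
  if (is.null(cfg$design) || is.null(cfg$factors)) {
    stop("robustness workflow needs 'design' and 'factors' paths",
         call. = FALSE)
  }
  factors <- read_factor_specs(cfg$factors)
  design <- read_design(cfg$design, factors)
  validation <- validate_design(design)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(ok = validation$ok, balanced = as.list(validation$balanced),
         messages = validation$messages),
    file.path(out, "design_validation.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  if (!validation$ok) {
    stop(paste(c("design validation failed:", validation$messages),
               collapse = "\n  "), call. = FALSE)
  }
  table <- .preprocess(cfg)
  qc <- NULL
  if (any(table$samples$role == "qc")) {
    qc <- qc_drift_check(table, threshold = cfg$qc_drift_threshold)
    jsonlite::write_json(
      list(median_abs_slope = qc$median_abs_slope,
           threshold = qc$threshold, pass = qc$pass),
      file.path(out, "qc_drift.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
  }
  table <- drop_blank_features(table)
  dataset <- assemble_robustness_dataset(table, design)
  mc <- cfg$model
  config_obj <- model_config(
    variant = if (!is.null(mc$variant)) mc$variant else "pooled",
    method = if (!is.null(mc$method)) mc$method else "map",
    prior_scale_beta = if (!is.null(mc$prior_scale_beta))
      mc$prior_scale_beta else 1,
    prior_scale_tau = if (!is.null(mc$prior_scale_tau))
      mc$prior_scale_tau else 1,
    prior_scale_sigma = if (!is.null(mc$prior_scale_sigma))
      mc$prior_scale_sigma else 1,
    iter = if (!is.null(mc$iter)) mc$iter else 1000L,
    burn = if (!is.null(mc$burn)) mc$burn else 250L,
    seed = cfg$seed)
  estimates <- if (config_obj$variant == "per_metabolite") {
    fit_per_metabolite_model(dataset, config_obj)
  } else {
    fit_pooled_model(dataset, config_obj)
  }
  write_effect_estimates(estimates,
                         csv_path = file.path(out, "effect_estimates.csv"),
                         json_path = file.path(out, "effect_estimates.json"))
  jsonlite::write_json(.provenance(cfg, cfg$seed),
                       file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(estimates = estimates, qc_drift = qc,
                 validation = validation, dataset = dataset))
}
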