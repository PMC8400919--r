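#' Configuration for the synthetic LC-MS data generator
#'
#' Defines the ground-truth parameters of a simulated untargeted LC-MS
#' batch. Baseline log abundances are drawn once per feature from
#' Normal(`baseline_log_mean`, `baseline_log_sd`); replicate noise is
#' multiplicative log-normal with log-sd `sqrt(log(1 + cv^2))` so the
#' target coefficient of variation holds exactly in expectation; design
#' factor effects act multiplicatively on the log scale; contaminant
#' features appear in blanks as well as study samples; dropout removes
#' detected cells at random; and feature m/z and retention times are
#' jittered uniformly within the stated scales around their true seeds.
#'
#' Defaults emulate a tumour-extract batch: a few hundred features spanning
#' the instrument's mass range, baseline signals a few hundred-fold above
#' the 200-count noise floor, 10% replicate CV (a reproducible protocol),
#' no dropout and a handful of solvent contaminants.
#'
#' @param n_features Number of true study features.
#' @param baseline_log_mean,baseline_log_sd Natural-log baseline abundance
#'   distribution (defaults `log(5e4)` and 1).
#' @param cv_percent Target replicate CV in percent (default 10).
#' @param true_beta Named or positional numeric vector of log-scale factor
#'   effects (recycled/zero-padded to the design's factor count).
#' @param dropout Per-cell probability a detected study feature is missing.
#' @param n_blank_contaminants Number of extra contaminant features present
#'   in blanks and study samples.
#' @param mz_range,rt_range Ranges the true feature seeds are drawn from
#'   (Da; minutes).
#' @param mz_jitter_ppm,rt_jitter_min Half-widths of the uniform
#'   measurement jitter applied per observed peak (defaults 5 ppm and 0.05
#'   min, comfortably inside the 15 ppm / 0.15 min alignment tolerances).
#' @param qc_drift_per_injection Multiplicative log-scale drift per
#'   injection applied to QC samples (0 = stable instrument).
#' @param seed Integer seed fixing all randomness.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_features = 300L,
                              baseline_log_mean = log(5e4),
                              baseline_log_sd = 1,
                              cv_percent = 10,
                              true_beta = numeric(0),
                              dropout = 0,
                              n_blank_contaminants = 10L,
                              mz_range = c(100, 1000),
                              rt_range = c(0.5, 30),
                              mz_jitter_ppm = 5,
                              rt_jitter_min = 0.05,
                              qc_drift_per_injection = 0,
                              seed = 1L) {
  stopifnot(n_features >= 1L, cv_percent >= 0, dropout >= 0, dropout <= 1,
            n_blank_contaminants >= 0, mz_jitter_ppm >= 0,
            rt_jitter_min >= 0, length(mz_range) == 2L,
            length(rt_range) == 2L, baseline_log_sd >= 0)
  structure(list(n_features = as.integer(n_features),
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 cv_percent = cv_percent,
                 true_beta = true_beta,
                 dropout = dropout,
                 n_blank_contaminants = as.integer(n_blank_contaminants),
                 mz_range = mz_range, rt_range = rt_range,
                 mz_jitter_ppm = mz_jitter_ppm,
                 rt_jitter_min = rt_jitter_min,
                 qc_drift_per_injection = qc_drift_per_injection,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.noise_sd_from_cv <- function(cv_percent) {
  cv <- cv_percent / 100
  sqrt(log(1 + cv^2))
}

.draw_feature_seeds <- function(n, config) {
  data.frame(
    mz = sort(stats::runif(n, config$mz_range[1], config$mz_range[2])),
    rt = stats::runif(n, config$rt_range[1], config$rt_range[2]),
    baseline = stats::rnorm(n, config$baseline_log_mean,
                            config$baseline_log_sd))
}

.jitter_peaks <- function(mz, rt, config) {
  list(mz = mz * (1 + stats::runif(length(mz), -config$mz_jitter_ppm,
                                   config$mz_jitter_ppm) * 1e-6),
       rt = pmax(0, rt + stats::runif(length(rt), -config$rt_jitter_min,
                                      config$rt_jitter_min)))
}

#' Simulate a Plackett-Burman robustness experiment
#'
#' Generates one peak list per design run plus blank extractions and
#' repeated QC injections (one QC every `qc_every` study samples, from the
#' same virtual vial), with abundance of feature `m` in run `i` equal to
#' `exp(baseline[m] + sum_f beta[f] * x[i,f] + noise)`. Contaminant
#' features carry no design effect and appear in blanks too. All
#' randomness derives from `config$seed`; the recorded ground truth
#' (true feature seeds, betas, contaminant ids, dropout mask) is returned
#' alongside the data.
#'
#' @param design A `design_matrix` (typically 12 factorial + 3 centre runs).
#' @param config A [simulation_config()].
#' @param n_blanks Number of blank extractions (default 2).
#' @param qc_every Inject a QC after every this many study samples
#'   (default 4).
#' @return List with `peak_lists` (list of `peak_list`), `ground_truth`
#'   (list: `features` data frame with true mz/rt/baseline, `true_beta`,
#'   `contaminant_ids`, `dropout_mask`), and `design`.
#' @export
simulate_robustness_experiment <- function(design, config, n_blanks = 2L,
                                           qc_every = 4L) {
  stopifnot(inherits(design, "design_matrix"),
            inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_run <- nrow(design$coded)
  f <- ncol(design$coded)
  beta <- rep(0, f)
  tb <- config$true_beta
  if (length(tb)) {
    if (!is.null(names(tb))) {
      idx <- match(names(tb), colnames(design$coded))
      if (anyNA(idx)) stop("true_beta names not in design factors",
                           call. = FALSE)
      beta[idx] <- tb
    } else {
      beta[seq_along(tb)] <- tb
    }
  }
  n_study <- config$n_features
  n_cont <- config$n_blank_contaminants
  seeds <- .draw_feature_seeds(n_study + n_cont, config)
  cont_ids <- if (n_cont > 0L) {
    sort(sample.int(n_study + n_cont, n_cont))
  } else integer(0)
  is_cont <- seq_len(n_study + n_cont) %in% cont_ids
  sd_noise <- .noise_sd_from_cv(config$cv_percent)

  run_effect <- as.vector(design$coded %*% beta)   # per run, log scale
  peak_lists <- list()
  dropout_mask <- matrix(FALSE, n_study + n_cont, n_run,
                         dimnames = list(NULL, design$run_ids))
  inj <- 0L
  qc_counter <- 0L
  emit_qc <- function(inj) {
    log_ab <- seeds$baseline +
      config$qc_drift_per_injection * inj +
      stats::rnorm(nrow(seeds), 0, sd_noise / 4)
    jit <- .jitter_peaks(seeds$mz, seeds$rt, config)
    peak_list(sample_id = sprintf("QC_%02d", inj), role = "qc",
              injection_order = inj,
              peaks = data.frame(mz = jit$mz, rt = jit$rt,
                                 abundance = exp(log_ab)))
  }
  for (i in seq_len(n_run)) {
    inj <- inj + 1L
    if (i == 1L || qc_counter == qc_every) {  # QC leads the batch and
      peak_lists[[length(peak_lists) + 1L]] <- emit_qc(inj)  # every 4 samples
      qc_counter <- 0L
      inj <- inj + 1L
    }
    log_ab <- seeds$baseline + ifelse(is_cont, 0, run_effect[i]) +
      stats::rnorm(nrow(seeds), 0, sd_noise)
    drop <- !is_cont & stats::runif(nrow(seeds)) < config$dropout
    dropout_mask[, i] <- drop
    keep <- which(!drop)
    jit <- .jitter_peaks(seeds$mz[keep], seeds$rt[keep], config)
    peak_lists[[length(peak_lists) + 1L]] <- peak_list(
      sample_id = sprintf("RUN_%02d", design$run_ids[i]), role = "study",
      design_run = design$run_ids[i], injection_order = inj,
      peaks = data.frame(mz = jit$mz, rt = jit$rt,
                         abundance = exp(log_ab[keep])))
    qc_counter <- qc_counter + 1L
  }
  inj <- inj + 1L
  peak_lists[[length(peak_lists) + 1L]] <- emit_qc(inj)  # closing QC
  for (b in seq_len(n_blanks)) {
    inj <- inj + 1L
    keep <- cont_ids
    jit <- .jitter_peaks(seeds$mz[keep], seeds$rt[keep], config)
    log_ab <- seeds$baseline[keep] + stats::rnorm(length(keep), 0, sd_noise)
    peak_lists[[length(peak_lists) + 1L]] <- peak_list(
      sample_id = sprintf("BLANK_%02d", b), role = "blank",
      injection_order = inj,
      peaks = data.frame(mz = jit$mz, rt = jit$rt, abundance = exp(log_ab)))
  }
  names(peak_lists) <- vapply(peak_lists, `[[`, character(1), "sample_id")
  list(peak_lists = peak_lists,
       ground_truth = list(features = seeds,
                           true_beta = stats::setNames(beta,
                                                       colnames(design$coded)),
                           contaminant_ids = cont_ids,
                           dropout_mask = dropout_mask),
       design = design)
}

#' Simulate an extraction-method comparison experiment
#'
#' Each method detects a subset of a shared feature universe (controllable
#' overlap) and measures it with its own replicate CV, mimicking protocols
#' of different reproducibility; blanks carry the shared contaminants.
#'
#' @param configs Named list of [simulation_config()]s, one per method.
#'   Per-method fields used: `cv_percent`, `dropout`; the first config
#'   fixes the universe (`n_features`, ranges, jitter, contaminants, seed).
#' @param detect_prob Probability each method detects a universe feature
#'   (scalar or per-method vector; default 0.9). Detection sets are drawn
#'   independently per method.
#' @param n_replicates Replicates per method (default 3).
#' @param n_blanks Number of blank extractions (default 2).
#' @return List with `peak_lists`, `ground_truth` (universe features,
#'   per-method detection sets, contaminant ids) — same CSV-ready
#'   structures as the robustness simulator.
#' @export
simulate_method_comparison <- function(configs, detect_prob = 0.9,
                                       n_replicates = 3L, n_blanks = 2L) {
  stopifnot(is.list(configs), length(configs) >= 1L,
            !is.null(names(configs)),
            all(vapply(configs, inherits, logical(1), "simulation_config")))
  methods <- names(configs)
  base <- configs[[1L]]
  set.seed(base$seed)
  detect_prob <- rep(detect_prob, length.out = length(methods))
  n_feat <- base$n_features
  n_cont <- base$n_blank_contaminants
  seeds <- .draw_feature_seeds(n_feat + n_cont, base)
  cont_ids <- if (n_cont > 0L) sort(sample.int(n_feat + n_cont, n_cont))
              else integer(0)
  study_ids <- setdiff(seq_len(n_feat + n_cont), cont_ids)
  detected <- lapply(seq_along(methods), function(k) {
    if (configs[[k]]$dropout >= 1) return(integer(0))
    sort(study_ids[stats::runif(length(study_ids)) < detect_prob[k]])
  })
  names(detected) <- methods
  peak_lists <- list()
  inj <- 0L
  for (k in seq_along(methods)) {
    cfg <- configs[[k]]
    sd_noise <- .noise_sd_from_cv(cfg$cv_percent)
    ids <- union(detected[[k]], cont_ids)
    for (r in seq_len(n_replicates)) {
      inj <- inj + 1L
      drop <- stats::runif(length(ids)) < cfg$dropout &
        !(ids %in% cont_ids)
      keep <- ids[!drop]
      jit <- .jitter_peaks(seeds$mz[keep], seeds$rt[keep], base)
      log_ab <- seeds$baseline[keep] +
        stats::rnorm(length(keep), 0, sd_noise)
      peak_lists[[length(peak_lists) + 1L]] <- peak_list(
        sample_id = sprintf("%s_R%d", methods[k], r), role = "study",
        method = methods[k], replicate = r, injection_order = inj,
        peaks = data.frame(mz = jit$mz, rt = jit$rt,
                           abundance = exp(log_ab)))
    }
  }
  for (b in seq_len(n_blanks)) {
    inj <- inj + 1L
    jit <- .jitter_peaks(seeds$mz[cont_ids], seeds$rt[cont_ids], base)
    log_ab <- seeds$baseline[cont_ids] +
      stats::rnorm(length(cont_ids), 0, .noise_sd_from_cv(base$cv_percent))
    peak_lists[[length(peak_lists) + 1L]] <- peak_list(
      sample_id = sprintf("BLANK_%02d", b), role = "blank",
      injection_order = inj,
      peaks = data.frame(mz = jit$mz, rt = jit$rt, abundance = exp(log_ab)))
  }
  names(peak_lists) <- vapply(peak_lists, `[[`, character(1), "sample_id")
  list(peak_lists = peak_lists,
       ground_truth = list(features = seeds, detected = detected,
                           contaminant_ids = cont_ids))
}

#' Write simulated peak lists and metadata to CSV
#'
#' Emits the same CSV dialects [read_peak_lists()] consumes: one peaks file
#' (`sample_id, mz, rt, abundance`) and one metadata file; ground truth, if
#' given, is written as JSON.
#'
#' @param peak_lists List of `peak_list` objects.
#' @param dir Output directory (created if needed).
#' @param ground_truth Optional ground-truth list to serialize.
#' @return Named character vector of the paths written.
#' @export
write_peak_lists <- function(peak_lists, dir, ground_truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  peaks <- do.call(rbind, lapply(peak_lists, function(p) {
    if (nrow(p$peaks) == 0L) return(NULL)
    cbind(sample_id = p$sample_id, p$peaks)
  }))
  meta <- data.frame(
    sample_id = vapply(peak_lists, `[[`, character(1), "sample_id"),
    role = vapply(peak_lists, `[[`, character(1), "role"),
    method = vapply(peak_lists, function(p) as.character(p$method),
                    character(1)),
    replicate = vapply(peak_lists, function(p) as.integer(p$replicate)[1],
                       integer(1)),
    design_run = vapply(peak_lists, function(p) as.character(p$design_run),
                        character(1)),
    injection_order = vapply(peak_lists,
                             function(p) as.integer(p$injection_order)[1],
                             integer(1)),
    row.names = NULL)
  paths <- c(peaks = file.path(dir, "peaks.csv"),
             metadata = file.path(dir, "metadata.csv"))
  utils::write.csv(peaks, paths["peaks"], row.names = FALSE)
  utils::write.csv(meta, paths["metadata"], row.names = FALSE)
  if (!is.null(ground_truth)) {
    paths["ground_truth"] <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(ground_truth, paths["ground_truth"],
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  paths
}
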