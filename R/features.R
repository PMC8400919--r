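#' Read per-sample LC-MS peak lists with sample metadata
#'
#' Peak lists are delimited text with columns `sample_id, mz, rt, abundance`
#' (one or several files; a file may hold several samples). Metadata is a
#' data frame or CSV with columns `sample_id, role, method, replicate,
#' design_run, injection_order`; `role` is one of `study`, `blank`, `qc`.
#'
#' @param paths Character vector of peak-list CSV paths.
#' @param metadata Data frame or path to a metadata CSV covering every
#'   `sample_id` present in the peak lists.
#' @return A list of `peak_list` objects (one per sample), each a list with
#'   `sample_id`, `role`, `method`, `replicate`, `design_run`,
#'   `injection_order` and a data frame `peaks` (`mz`, `rt`, `abundance`).
#' @export
read_peak_lists <- function(paths, metadata) {
  if (is.character(metadata)) {
    if (!file.exists(metadata)) {
      stop(sprintf("metadata file not found: %s", metadata), call. = FALSE)
    }
    metadata <- utils::read.csv(metadata, check.names = FALSE)
  }
  need <- c("sample_id", "role", "injection_order")
  if (!all(need %in% names(metadata))) {
    stop(sprintf("metadata lacks columns: %s",
                 paste(setdiff(need, names(metadata)), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  if (anyDuplicated(metadata$injection_order)) {
    stop("duplicate injection_order in metadata", call. = FALSE)
  }
  rows <- list()
  for (p in paths) {
    if (!file.exists(p)) stop(sprintf("peak list not found: %s", p),
                              call. = FALSE)
    df <- utils::read.csv(p, check.names = FALSE)
    req <- c("sample_id", "mz", "rt", "abundance")
    if (!all(req %in% names(df))) {
      stop(sprintf("%s: peak list needs columns %s", p,
                   paste(req, collapse = ", ")), call. = FALSE)
    }
    bad <- which(!is.finite(df$mz) | df$mz <= 0 |
                   !is.finite(df$rt) | df$rt < 0 |
                   !is.finite(df$abundance) | df$abundance < 0)
    if (length(bad)) {
      stop(sprintf("%s: malformed peak rows (line %s): mz must be > 0, rt and abundance >= 0",
                   p, paste(bad[seq_len(min(5L, length(bad)))] + 1L,
                            collapse = ", ")), call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- df
  }
  all_peaks <- do.call(rbind, rows)
  missing_meta <- setdiff(unique(all_peaks$sample_id), metadata$sample_id)
  if (length(missing_meta)) {
    stop(sprintf("metadata missing sample id(s): %s",
                 paste(missing_meta, collapse = ", ")), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(metadata)), function(i) {
    sid <- metadata$sample_id[i]
    pk <- all_peaks[all_peaks$sample_id == sid, c("mz", "rt", "abundance"),
                    drop = FALSE]
    rownames(pk) <- NULL
    peak_list(sample_id = sid,
              role = metadata$role[i],
              method = if ("method" %in% names(metadata))
                metadata$method[i] else NA_character_,
              replicate = if ("replicate" %in% names(metadata))
                metadata$replicate[i] else NA_integer_,
              design_run = if ("design_run" %in% names(metadata))
                metadata$design_run[i] else NA,
              injection_order = metadata$injection_order[i],
              peaks = pk)
  })
  names(out) <- metadata$sample_id
  out
}

#' Construct a peak list object
#'
#' @param sample_id Unique sample identifier.
#' @param role `"study"`, `"blank"` or `"qc"`.
#' @param method Extraction-method label (or `NA`).
#' @param replicate Replicate index within method (or `NA`).
#' @param design_run Design run id for robustness samples (or `NA`).
#' @param injection_order Integer position in the analytical batch.
#' @param peaks Data frame with numeric `mz`, `rt`, `abundance`.
#' @return A `peak_list`.
#' @export
peak_list <- function(sample_id, role = "study", method = NA_character_,
                      replicate = NA_integer_, design_run = NA,
                      injection_order = NA_integer_,
                      peaks = data.frame(mz = numeric(0), rt = numeric(0),
                                         abundance = numeric(0))) {
  role <- match.arg(role, c("study", "blank", "qc"))
  stopifnot(is.data.frame(peaks),
            all(c("mz", "rt", "abundance") %in% names(peaks)))
  if (nrow(peaks) && (any(peaks$mz <= 0) || any(peaks$abundance < 0))) {
    stop("peaks must have mz > 0 and abundance >= 0", call. = FALSE)
  }
  structure(list(sample_id = sample_id, role = role, method = method,
                 replicate = replicate, design_run = design_run,
                 injection_order = injection_order,
                 peaks = peaks[, c("mz", "rt", "abundance")]),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %s (%s): %d peaks\n", x$sample_id, x$role,
              nrow(x$peaks)))
  invisible(x)
}

#' Remove background-noise signals from a peak list
#'
#' Signals strictly below the threshold are treated as instrument background
#' and removed; a peak exactly at the threshold is retained. The conventional
#' TOF noise floor of 200 counts is the default.
#'
#' @param peaklist A `peak_list`.
#' @param threshold Noise threshold in counts (default 200).
#' @return The filtered `peak_list`.
#' @examples
#' pl <- peak_list("s1", peaks = data.frame(mz = c(100, 200),
#'                                          rt = c(1, 2),
#'                                          abundance = c(150, 200)))
#' nrow(noise_filter(pl)$peaks)  # 1: the 150-count peak is noise
#' @export
noise_filter <- function(peaklist, threshold = 200) {
  stopifnot(inherits(peaklist, "peak_list"), threshold >= 0)
  keep <- peaklist$peaks$abundance >= threshold
  peaklist$peaks <- peaklist$peaks[keep, , drop = FALSE]
  rownames(peaklist$peaks) <- NULL
  peaklist
}

#' Align peaks across samples into a feature table
#'
#' Greedy centroid clustering: all peaks from all samples are visited in
#' descending abundance order and each joins the existing feature whose
#' consensus m/z lies within `ppm_tol` parts per million and whose consensus
#' retention time lies within `rt_tol_min` minutes — provided that feature
#' has no peak from the same sample yet. Among multiple candidates the
#' smallest ppm distance wins, ties broken by rt distance, then by lower
#' feature id; otherwise the peak seeds a new feature. Consensus m/z and rt
#' are abundance-weighted means of member peaks and are updated as members
#' join. The procedure is deterministic for fixed input (the visiting order
#' breaks abundance ties by m/z, rt, then sample id).
#'
#' @param peaklists List of `peak_list` objects.
#' @param ppm_tol Mass tolerance in ppm (default 15).
#' @param rt_tol_min Retention-time tolerance in minutes (default 0.15).
#' @return A `feature_table`: list with `features` (data frame `feature_id`,
#'   `mz`, `rt`, `adduct_group`), `samples` (metadata data frame) and
#'   `abundance` (features x samples matrix, `NA` marks a missing value).
#' @export
align_features <- function(peaklists, ppm_tol = 15, rt_tol_min = 0.15) {
  stopifnot(length(peaklists) >= 1L, ppm_tol > 0, rt_tol_min > 0)
  stopifnot(all(vapply(peaklists, inherits, logical(1), "peak_list")))
  samples <- data.frame(
    sample_id = vapply(peaklists, `[[`, character(1), "sample_id"),
    role = vapply(peaklists, `[[`, character(1), "role"),
    method = vapply(peaklists, function(p) as.character(p$method),
                    character(1)),
    replicate = vapply(peaklists, function(p) as.integer(p$replicate)[1],
                       integer(1)),
    design_run = vapply(peaklists, function(p) as.character(p$design_run),
                        character(1)),
    injection_order = vapply(peaklists,
                             function(p) as.integer(p$injection_order)[1],
                             integer(1)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample ids across peak lists", call. = FALSE)
  }
  pk <- do.call(rbind, lapply(seq_along(peaklists), function(i) {
    p <- peaklists[[i]]$peaks
    if (nrow(p) == 0L) return(NULL)
    cbind(p, sample = i)
  }))
  n_samp <- nrow(samples)
  if (is.null(pk) || nrow(pk) == 0L) {
    return(.new_feature_table(
      data.frame(feature_id = character(0), mz = numeric(0), rt = numeric(0),
                 adduct_group = integer(0)),
      samples, matrix(NA_real_, 0L, n_samp)))
  }
  ord <- order(-pk$abundance, pk$mz, pk$rt,
               samples$sample_id[pk$sample], method = "radix")
  pk <- pk[ord, ]

  n <- nrow(pk)
  # feature state, grown geometrically
  cap <- 64L
  f_mz <- f_rt <- f_w <- numeric(cap)   # consensus and total weight
  member <- vector("list", cap)         # per-feature sample -> row index map
  n_feat <- 0L
  assign_feat <- integer(n)
  for (j in seq_len(n)) {
    mz <- pk$mz[j]; rt <- pk$rt[j]; ab <- pk$abundance[j]; sm <- pk$sample[j]
    best <- 0L; best_ppm <- Inf; best_rt <- Inf
    if (n_feat > 0L) {
      idx <- seq_len(n_feat)
      dppm <- abs(mz - f_mz[idx]) / f_mz[idx] * 1e6
      drt <- abs(rt - f_rt[idx])
      cand <- which(dppm <= ppm_tol & drt <= rt_tol_min)
      for (k in cand) {
        if (!is.null(member[[k]][[as.character(sm)]])) next  # one peak/sample
        if (dppm[k] < best_ppm ||
            (dppm[k] == best_ppm && drt[k] < best_rt)) {
          best <- k; best_ppm <- dppm[k]; best_rt <- drt[k]
        }
      }
    }
    if (best == 0L) {
      n_feat <- n_feat + 1L
      if (n_feat > cap) {
        cap <- cap * 2L
        length(f_mz) <- cap; length(f_rt) <- cap; length(f_w) <- cap
        length(member) <- cap
      }
      best <- n_feat
      f_mz[best] <- mz; f_rt[best] <- rt; f_w[best] <- ab
      member[[best]] <- list()
    } else {
      # abundance-weighted consensus update (zero-abundance peaks count as
      # weight 0 and leave the consensus where it is)
      w <- f_w[best] + ab
      if (w > 0) {
        f_mz[best] <- (f_mz[best] * f_w[best] + mz * ab) / w
        f_rt[best] <- (f_rt[best] * f_w[best] + rt * ab) / w
      }
      f_w[best] <- w
    }
    member[[best]][[as.character(sm)]] <- j
    assign_feat[j] <- best
  }

  keep <- seq_len(n_feat)
  ordf <- keep[order(f_mz[keep], f_rt[keep])]
  abund <- matrix(NA_real_, length(ordf), n_samp)
  for (new_id in seq_along(ordf)) {
    k <- ordf[new_id]
    for (sm in names(member[[k]])) {
      abund[new_id, as.integer(sm)] <- pk$abundance[member[[k]][[sm]]]
    }
  }
  colnames(abund) <- samples$sample_id
  features <- data.frame(
    feature_id = sprintf("F%04d", seq_along(ordf)),
    mz = f_mz[ordf], rt = f_rt[ordf],
    adduct_group = NA_integer_,
    stringsAsFactors = FALSE)
  .new_feature_table(features, samples, abund)
}

.new_feature_table <- function(features, samples, abundance) {
  rownames(abundance) <- features$feature_id
  structure(list(features = features, samples = samples,
                 abundance = abundance),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples (%.1f%% missing)\n",
              nrow(x$features), nrow(x$samples),
              100 * mean(is.na(x$abundance))))
  invisible(x)
}

#' Construct a feature table directly
#'
#' Mostly useful in tests and simulations; [align_features()] is the usual
#' constructor.
#'
#' @param features Data frame with `feature_id`, `mz`, `rt` (and optionally
#'   `adduct_group`).
#' @param samples Data frame with at least `sample_id` and `role`.
#' @param abundance Numeric matrix, features x samples; `NA` = not detected.
#' @return A `feature_table`.
#' @export
feature_table <- function(features, samples, abundance) {
  stopifnot(is.data.frame(features), is.data.frame(samples),
            is.matrix(abundance),
            nrow(abundance) == nrow(features),
            ncol(abundance) == nrow(samples),
            all(c("feature_id", "mz", "rt") %in% names(features)),
            "sample_id" %in% names(samples))
  if (!"role" %in% names(samples)) samples$role <- "study"
  if (!"adduct_group" %in% names(features)) {
    features$adduct_group <- NA_integer_
  }
  colnames(abundance) <- samples$sample_id
  .new_feature_table(features, samples, abundance)
}

#' Write / read a feature table as CSV
#'
#' First three columns are `feature_id`, `mz`, `rt`, then one column per
#' sample; missing abundances are empty cells. Numeric fields round-trip at
#' full precision. Sample metadata is written alongside as
#' `<path>.samples.csv` and read back from there.
#'
#' @param table A `feature_table`.
#' @param path Output CSV path.
#' @return `write_feature_table`: `path`, invisibly. `read_feature_table`:
#'   a `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  ab <- format(table$abundance, digits = 17, trim = TRUE, scientific = FALSE)
  ab[is.na(table$abundance)] <- ""
  df <- cbind(table$features[, c("feature_id", "mz", "rt")],
              as.data.frame(ab, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(table$samples, paste0(path, ".samples.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("feature table not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  spath <- paste0(path, ".samples.csv")
  if (!file.exists(spath)) {
    stop(sprintf("sample metadata not found: %s", spath), call. = FALSE)
  }
  samples <- utils::read.csv(spath, check.names = FALSE,
                             colClasses = c(sample_id = "character"))
  sample_cols <- setdiff(names(df), c("feature_id", "mz", "rt"))
  if (!identical(sort(sample_cols), sort(as.character(samples$sample_id)))) {
    stop("feature table columns do not match sample metadata", call. = FALSE)
  }
  ab <- as.matrix(df[, as.character(samples$sample_id), drop = FALSE])
  storage.mode(ab) <- "double"
  feature_table(df[, c("feature_id", "mz", "rt")], samples, ab)
}

# Monoisotopic masses (Da) of the charge carriers / losses considered per
# ionization mode. Values are the mass shifts of the ion species relative to
# the neutral molecule M.
.adduct_shifts <- function(mode) {
  switch(mode,
    positive = c("M+H" = 1.00727646, "M+Na" = 22.98922142,
                 "M+K" = 38.96315842, "M+NH4" = 18.03382555,
                 "M+H-H2O" = 1.00727646 - 18.01056468),
    negative = c("M-H" = -1.00727646, "M+HCOO" = 44.99820285,
                 "M+Cl" = 34.96885271,
                 "M-H-H2O" = -1.00727646 - 18.01056468),
    stop("mode must be 'positive' or 'negative'", call. = FALSE))
}

#' Annotate adduct groups among aligned features
#'
#' Two features are tied to the same adduct group when they co-elute (their
#' consensus retention times differ by at most `rt_tol_min`) and their m/z
#' difference matches, within `ppm_tol`, a pairwise difference of the
#' mode's adduct mass shifts (positive mode: H+, Na+, K+, NH4+ and neutral
#' water loss; negative mode: H-, HCOO-, Cl- and water loss). Grouping is the
#' transitive closure of these pairwise ties. Annotation is informational:
#' abundances are never merged.
#'
#' @param table A `feature_table`.
#' @param mode `"positive"` or `"negative"` ionization.
#' @param ppm_tol Mass tolerance in ppm (default 15).
#' @param rt_tol_min Co-elution tolerance in minutes (default 0.15).
#' @return The table with `features$adduct_group` filled in (integer ids;
#'   singletons get their own group).
#' @export
annotate_adduct_groups <- function(table, mode = c("positive", "negative"),
                                   ppm_tol = 15, rt_tol_min = 0.15) {
  stopifnot(inherits(table, "feature_table"))
  mode <- match.arg(mode)
  shifts <- .adduct_shifts(mode)
  deltas <- unique(round(c(
    abs(outer(shifts, shifts, "-"))[upper.tri(diag(length(shifts)))],
    18.01056468), 6))  # water loss also links M+X to M+X-H2O at any X
  deltas <- deltas[deltas > 0]
  n <- nrow(table$features)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  mz <- table$features$mz; rt <- table$features$rt
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (abs(rt[i] - rt[j]) > rt_tol_min) next
        dmz <- abs(mz[i] - mz[j])
        tol <- ppm_tol * 1e-6 * max(mz[i], mz[j])
        if (any(abs(dmz - deltas) <= tol)) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  table$features$adduct_group <- match(roots, unique(roots))
  table
}
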