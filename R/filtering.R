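#' Discard features detected in blank extractions
#'
#' A feature with a non-missing abundance in any blank sample is treated as
#' solvent/reagent contamination and removed outright (no fold-change rule).
#' The blank columns themselves are dropped from the returned table.
#'
#' @param table A `feature_table`.
#' @param blank_sample_ids Character vector of blank sample ids; defaults to
#'   the samples whose metadata role is `"blank"`.
#' @return The filtered `feature_table` without blank columns.
#' @export
drop_blank_features <- function(table,
                                blank_sample_ids =
                                  table$samples$sample_id[
                                    table$samples$role == "blank"]) {
  stopifnot(inherits(table, "feature_table"))
  unknown <- setdiff(blank_sample_ids, table$samples$sample_id)
  if (length(unknown)) {
    stop(sprintf("unknown blank sample id(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  bcol <- table$samples$sample_id %in% blank_sample_ids
  in_blank <- if (any(bcol)) {
    rowSums(!is.na(table$abundance[, bcol, drop = FALSE])) > 0L
  } else {
    rep(FALSE, nrow(table$features))
  }
  feature_table(table$features[!in_blank, , drop = FALSE],
                table$samples[!bcol, , drop = FALSE],
                table$abundance[!in_blank, !bcol, drop = FALSE])
}

#' Features present in every replicate of a group
#'
#' A feature counts as extracted by a method only if it was detected
#' (non-missing abundance) in all of the method's replicate samples.
#'
#' @param table A `feature_table`.
#' @param group Method label; the group's samples are those with
#'   `samples$method == group` (and role `"study"`).
#' @return Character vector of feature ids detected in every replicate.
#' @export
replicate_presence_filter <- function(table, group) {
  stopifnot(inherits(table, "feature_table"))
  cols <- which(table$samples$method == group &
                  table$samples$role == "study")
  if (length(cols) == 0L) {
    stop(sprintf("no samples for group '%s'", group), call. = FALSE)
  }
  if (length(cols) == 1L) {
    warning(sprintf("group '%s' has a single replicate; presence in that one sample suffices",
                    group), call. = FALSE)
  }
  present <- rowSums(!is.na(table$abundance[, cols, drop = FALSE])) ==
    length(cols)
  table$features$feature_id[present]
}

#' Coefficient of variation, in percent
#'
#' 100 x sample standard deviation (n-1 denominator) / arithmetic mean.
#' Undefined (error) for fewer than two values or a zero mean.
#'
#' @param abundances Numeric vector of non-negative, non-missing values.
#' @return CV as a percentage.
#' @examples
#' feature_cv(c(90, 100, 110))  # 10
#' @export
feature_cv <- function(abundances) {
  if (anyNA(abundances)) stop("abundances must be non-missing", call. = FALSE)
  if (length(abundances) < 2L) {
    stop("CV undefined for fewer than 2 values", call. = FALSE)
  }
  m <- mean(abundances)
  if (m == 0) stop("CV undefined for zero mean", call. = FALSE)
  100 * stats::sd(abundances) / m
}

#' Per-feature abundance statistics within a replicate group
#'
#' @param table A `feature_table`.
#' @param group Method label (see [replicate_presence_filter()]).
#' @param feature_ids Features to summarise (default: all).
#' @return Data frame of class `feature_stats`: `feature_id`, `group`,
#'   `n_detected`, `mean_abundance`, `cv` (percent; `NA` when undefined,
#'   i.e. fewer than 2 detections or zero mean).
#' @export
feature_stats <- function(table, group,
                          feature_ids = table$features$feature_id) {
  stopifnot(inherits(table, "feature_table"))
  cols <- which(table$samples$method == group &
                  table$samples$role == "study")
  if (length(cols) == 0L) {
    stop(sprintf("no samples for group '%s'", group), call. = FALSE)
  }
  rows <- match(feature_ids, table$features$feature_id)
  if (anyNA(rows)) stop("unknown feature id(s)", call. = FALSE)
  sub <- table$abundance[rows, cols, drop = FALSE]
  n_det <- rowSums(!is.na(sub))
  mn <- rowMeans(sub, na.rm = TRUE)
  mn[n_det == 0L] <- NA_real_
  cv <- vapply(seq_along(rows), function(i) {
    x <- sub[i, !is.na(sub[i, ])]
    if (length(x) < 2L || mean(x) == 0) return(NA_real_)
    100 * stats::sd(x) / mean(x)
  }, numeric(1))
  structure(data.frame(feature_id = feature_ids,
                       group = rep_len(group, length(feature_ids)),
                       n_detected = n_det, mean_abundance = mn, cv = cv,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("feature_stats", "data.frame"))
}

#' Reproducibly measured features
#'
#' Features whose abundance CV across replicates is strictly below the
#' threshold; 20% is the conventional quality cut for untargeted
#' metabolomics. Features with undefined CV are never included.
#'
#' @param stats A `feature_stats` data frame from [feature_stats()].
#' @param cv_threshold_pct CV threshold in percent (default 20; strict `<`).
#' @return Character vector of feature ids.
#' @export
reproducible_features <- function(stats, cv_threshold_pct = 20) {
  stopifnot(is.data.frame(stats), all(c("feature_id", "cv") %in% names(stats)))
  stats$feature_id[!is.na(stats$cv) & stats$cv < cv_threshold_pct]
}

#' Run the full feature-quality cascade for one replicate group
#'
#' Blank exclusion, then all-replicate presence, then CV classification.
#' Stage counts are non-increasing by construction.
#'
#' @param table A `feature_table` (blanks still included).
#' @param group Method label.
#' @param cv_threshold_pct CV threshold in percent (default 20).
#' @return A `filter_report`: list with `group`, `stage_counts` (named:
#'   `input`, `post_blank`, `all_replicates`, `reproducible`), `stats`
#'   (the [feature_stats()] of the all-replicate features), and
#'   `dispositions` (per-feature data frame `feature_id`, `status`,
#'   `removed_by`).
#' @export
filter_cascade <- function(table, group, cv_threshold_pct = 20) {
  stopifnot(inherits(table, "feature_table"))
  input_ids <- table$features$feature_id
  post_blank <- drop_blank_features(table)
  pb_ids <- post_blank$features$feature_id
  present_ids <- replicate_presence_filter(post_blank, group)
  st <- feature_stats(post_blank, group, present_ids)
  rep_ids <- reproducible_features(st, cv_threshold_pct)
  status <- ifelse(input_ids %in% rep_ids, "reproducible",
            ifelse(input_ids %in% present_ids, "all_replicates",
            ifelse(input_ids %in% pb_ids, "post_blank", "blank")))
  removed_by <- c(blank = "blank_filter", post_blank = "replicate_presence",
                  all_replicates = "cv_threshold",
                  reproducible = NA_character_)[status]
  rep <- structure(
    list(group = group,
         stage_counts = c(input = length(input_ids),
                          post_blank = length(pb_ids),
                          all_replicates = length(present_ids),
                          reproducible = length(rep_ids)),
         cv_threshold_pct = cv_threshold_pct,
         stats = st,
         dispositions = data.frame(feature_id = input_ids, status = status,
                                   removed_by = unname(removed_by),
                                   stringsAsFactors = FALSE)),
    class = "filter_report")
  stopifnot(!is.unsorted(rev(rep$stage_counts)))  # cascade monotonicity
  rep
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> group %s: %d -> %d (blank) -> %d (replicates) -> %d (CV < %g%%)\n",
              x$group, x$stage_counts["input"], x$stage_counts["post_blank"],
              x$stage_counts["all_replicates"], x$stage_counts["reproducible"],
              x$cv_threshold_pct))
  invisible(x)
}

#' Serialize a filter report
#'
#' Writes the stage counts and per-feature dispositions as JSON and the
#' per-feature statistics as CSV.
#'
#' @param report A `filter_report`.
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the list written to JSON.
#' @export
write_filter_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "filter_report"))
  payload <- list(group = report$group,
                  cv_threshold_pct = report$cv_threshold_pct,
                  stage_counts = as.list(report$stage_counts),
                  dispositions = report$dispositions)
  if (!is.null(json_path)) {
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(csv_path)) {
    utils::write.csv(report$stats, csv_path, row.names = FALSE)
  }
  invisible(payload)
}
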