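#' Compare extraction methods on one feature table
#'
#' For each method: the number of extracted features (detected in all of the
#' method's replicates, after blank exclusion), the number of reproducible
#' features (CV strictly below the threshold), and the mean CV over the
#' extracted features (features with undefined CV are excluded from the
#' mean — with an all-replicate presence rule and >= 2 replicates every
#' extracted feature has a defined CV unless its mean is zero).
#'
#' @param table A `feature_table` (blanks may be present; they are excluded
#'   first).
#' @param methods Method labels to compare; defaults to all study-sample
#'   method labels in the table.
#' @param cv_threshold_pct CV threshold in percent (default 20).
#' @return A `comparison_summary`: list with `summary` (data frame `method`,
#'   `n_extracted`, `n_reproducible`, `mean_cv`), `feature_sets` (named list
#'   of extracted-feature id vectors) and `reports` (per-method
#'   `filter_report`s).
#' @export
summarize_methods <- function(table,
                              methods = unique(
                                table$samples$method[
                                  table$samples$role == "study"]),
                              cv_threshold_pct = 20) {
  stopifnot(inherits(table, "feature_table"), length(methods) >= 1L)
  reports <- lapply(methods, function(m)
    filter_cascade(table, m, cv_threshold_pct))
  names(reports) <- methods
  feature_sets <- lapply(reports, function(r)
    r$dispositions$feature_id[r$dispositions$status %in%
                                c("all_replicates", "reproducible")])
  summary <- data.frame(
    method = methods,
    n_extracted = vapply(reports, function(r)
      unname(r$stage_counts["all_replicates"]), numeric(1)),
    n_reproducible = vapply(reports, function(r)
      unname(r$stage_counts["reproducible"]), numeric(1)),
    mean_cv = vapply(reports, function(r)
      mean(r$stats$cv, na.rm = TRUE), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(summary = summary, feature_sets = feature_sets,
                 reports = reports),
            class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat("<comparison_summary>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Exclusive intersection counts (UpSet semantics)
#'
#' Every feature in the union of the sets is counted toward exactly one
#' combination: the set of methods that detected it. The counts therefore sum
#' to the size of the union. Combinations with zero features are reported
#' too, so the full 2^k - 1 breakdown is available for plotting.
#'
#' @param feature_sets Named list mapping method label to a vector of feature
#'   ids.
#' @return An `intersection_counts`: data frame `combination` (labels joined
#'   by `"&"` in the input's method order), `degree`, `count`, plus
#'   attribute `union_size`.
#' @examples
#' intersection_counts(list(A = c("f1", "f2"), B = "f2"))
#' @export
intersection_counts <- function(feature_sets) {
  stopifnot(is.list(feature_sets), length(feature_sets) >= 1L,
            !is.null(names(feature_sets)), all(nzchar(names(feature_sets))))
  methods <- names(feature_sets)
  k <- length(methods)
  universe <- unique(unlist(feature_sets, use.names = FALSE))
  membership <- vapply(feature_sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  # all non-empty subsets
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  names(subsets) <- methods
  key <- apply(membership, 1L, function(r) paste(as.integer(r), collapse = ""))
  skey <- apply(as.matrix(subsets), 1L, function(r)
    paste(as.integer(r), collapse = ""))
  tab <- table(key)
  counts <- as.integer(tab[skey])
  counts[is.na(counts)] <- 0L
  combo <- apply(as.matrix(subsets), 1L, function(r)
    paste(methods[r], collapse = "&"))
  out <- data.frame(combination = combo,
                    degree = rowSums(subsets),
                    count = counts,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$degree, out$combination), ]
  rownames(out) <- NULL
  stopifnot(sum(out$count) == length(universe))  # conservation
  structure(out, union_size = length(universe),
            class = c("intersection_counts", "data.frame"))
}

#' Serialize comparison outputs
#'
#' @param summary A `comparison_summary`.
#' @param counts An `intersection_counts` (optional).
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @return Invisibly, the list written to JSON.
#' @export
write_comparison <- function(summary, counts = NULL, json_path = NULL,
                             csv_path = NULL) {
  stopifnot(inherits(summary, "comparison_summary"))
  payload <- list(summary = summary$summary)
  if (!is.null(counts)) {
    payload$intersections <- as.data.frame(counts)
    payload$union_size <- attr(counts, "union_size")
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(csv_path)) {
    utils::write.csv(summary$summary, csv_path, row.names = FALSE)
  }
  invisible(payload)
}
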