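#' Factor specification for a screening design
#'
#' Describes the physical meaning of one design factor: its name, units and
#' the physical values taken at the coded low (-1), centre (0) and high (+1)
#' levels. Dummy factors carry no physical meaning; their "levels" are the
#' coded values themselves and they serve as an estimate of standard error in
#' a Plackett-Burman screen.
#'
#' @param name Short factor label.
#' @param units Unit string ("uL", "min", "degC", ...); empty for dummies.
#' @param low,centre,high Physical values at coded -1 / 0 / +1. Must be
#'   strictly increasing for real factors.
#' @param is_dummy Logical; `TRUE` for a dummy (error-estimating) factor.
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("MTBE2", "uL", 315, 320, 325)
#' factor_spec("Dummy Factor", is_dummy = TRUE)
#' @export
factor_spec <- function(name, units = "", low = -1, centre = 0, high = 1,
                        is_dummy = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is_dummy) {
    low <- -1; centre <- 0; high <- 1; units <- ""
  } else {
    if (!(is.numeric(low) && is.numeric(centre) && is.numeric(high))) {
      stop("factor levels must be numeric", call. = FALSE)
    }
    if (!(low < centre && centre < high)) {
      stop(sprintf("levels of factor '%s' must satisfy low < centre < high",
                   name), call. = FALSE)
    }
  }
  structure(
    list(name = name, units = units, low = low, centre = centre, high = high,
         is_dummy = is_dummy),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("<factor_spec> %s%s: %s / %s / %s%s\n", x$name,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              format(x$low), format(x$centre), format(x$high),
              if (x$is_dummy) " (dummy)" else ""))
  invisible(x)
}

# Standard cyclic Plackett-Burman generating rows (first rows; the design is
# completed by cyclic rotation plus one all-minus row).
.pb_generators <- list(
  `4`  = c(1, 1, -1),
  `8`  = c(1, 1, 1, -1, 1, -1, -1),
  `12` = c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1),
  `16` = c(1, 1, 1, 1, -1, 1, -1, 1, 1, -1, -1, 1, -1, -1, -1),
  `20` = c(1, 1, -1, -1, 1, 1, 1, 1, -1, 1, -1, 1, -1, -1, -1, -1, 1, 1, -1),
  `24` = c(1, 1, 1, 1, 1, -1, 1, -1, 1, 1, -1, -1, 1, 1, -1, -1, 1, -1, 1,
           -1, -1, -1, -1)
)

.new_design_matrix <- function(coded, factors, run_ids = NULL) {
  coded <- as.matrix(coded)
  if (is.null(run_ids)) run_ids <- seq_len(nrow(coded))
  stopifnot(length(factors) == ncol(coded))
  colnames(coded) <- vapply(factors, `[[`, character(1), "name")
  rownames(coded) <- NULL
  is_centre <- apply(coded == 0L, 1L, all)
  structure(
    list(coded = coded,
         factors = factors,
         run_ids = run_ids,
         pattern = apply(coded, 1L, .levels_to_pattern),
         is_centre = is_centre,
         n_factorial = sum(!is_centre),
         n_centre = sum(is_centre)),
    class = "design_matrix"
  )
}

.levels_to_pattern <- function(lev) {
  if (all(lev == 0L)) return("0")
  paste(c("-", "0", "+")[lev + 2L], collapse = "")
}

.pattern_to_levels <- function(pattern, n_factors) {
  if (identical(pattern, "0")) return(rep(0L, n_factors))
  ch <- strsplit(chartr("−", "-", pattern), "")[[1]]
  if (length(ch) != n_factors) {
    stop(sprintf("pattern '%s' has %d symbols for %d factors",
                 pattern, length(ch), n_factors), call. = FALSE)
  }
  lev <- match(ch, c("-", "0", "+")) - 2L
  if (anyNA(lev)) stop(sprintf("pattern '%s' contains symbols outside -/0/+",
                               pattern), call. = FALSE)
  lev
}

#' Generate a Plackett-Burman screening design
#'
#' Builds the smallest standard Plackett-Burman design accommodating
#' `n_factors` two-level factors: `n` factorial runs where `n` is the smallest
#' multiple of 4 strictly greater than `n_factors`. The matrix is constructed
#' by cyclic rotation of the standard generating row plus an all-minus row,
#' then truncated to the first `n_factors` columns. Every column is balanced
#' (equal counts of -1 and +1) and every pair of columns is orthogonal, so the
#' design estimates main effects only. Ten real factors plus one dummy need 12
#' runs.
#'
#' @param factors Either a positive integer (number of factors; anonymous
#'   specs named F1..Fk are created) or a list of [factor_spec()] objects.
#' @param randomize_order Logical; randomize run execution order (off by
#'   default, the canonical cyclic order is kept).
#' @param seed Integer seed used only when `randomize_order = TRUE`.
#' @return A `design_matrix` with factorial runs only.
#' @examples
#' d <- generate_pb_matrix(11)  # ten study factors + one dummy -> 12 runs
#' d$n_factorial
#' @export
generate_pb_matrix <- function(factors, randomize_order = FALSE, seed = NULL) {
  if (is.numeric(factors) && length(factors) == 1L) {
    n_factors <- as.integer(factors)
    stopifnot(n_factors >= 1L)
    specs <- lapply(seq_len(n_factors),
                    function(i) factor_spec(paste0("F", i), "", -1, 0, 1))
  } else {
    specs <- factors
    stopifnot(all(vapply(specs, inherits, logical(1), "factor_spec")))
    n_factors <- length(specs)
  }
  n <- 4L * (n_factors %/% 4L + 1L)
  gen <- .pb_generators[[as.character(n)]]
  if (is.null(gen)) {
    stop(sprintf(
      "no Plackett-Burman generator for %d factors (max supported: %d)",
      n_factors, max(as.integer(names(.pb_generators))) - 1L), call. = FALSE)
  }
  k <- n - 1L
  gen <- as.integer(gen)
  rows <- t(vapply(0:(k - 1L),
                   function(s) gen[((seq_len(k) - 1L - s) %% k) + 1L],
                   integer(k)))
  coded <- rbind(rows, rep(-1L, k))[, seq_len(n_factors), drop = FALSE]
  if (randomize_order) {
    if (!is.null(seed)) set.seed(seed)
    coded <- coded[sample.int(nrow(coded)), , drop = FALSE]
  }
  .new_design_matrix(coded, specs)
}

#' Add centre-point runs to a design
#'
#' Centre points (all factors at coded 0) replicate the nominal protocol and
#' gauge measurement uncertainty. The default `"interleaved"` placement
#' spreads `k` centre runs evenly through the factorial runs, reproducing the
#' familiar worksheet layout in which 3 centre points among 12 factorial runs
#' sit at ordinal positions 6, 10 and 15.
#'
#' @param design A `design_matrix`.
#' @param k Non-negative number of centre runs to add.
#' @param placement `"interleaved"`, `"end"`, or an integer vector of target
#'   ordinal positions (length `k`) in the augmented design.
#' @return A `design_matrix` with `design$n_factorial + k` runs.
#' @export
add_centre_points <- function(design, k, placement = "interleaved") {
  stopifnot(inherits(design, "design_matrix"))
  k <- as.integer(k)
  if (k < 0L) stop("k must be non-negative", call. = FALSE)
  if (k == 0L) return(design)
  n0 <- nrow(design$coded)
  n_total <- n0 + k
  if (is.numeric(placement)) {
    pos <- as.integer(placement)
    stopifnot(length(pos) == k, all(pos >= 1L), all(pos <= n_total),
              !anyDuplicated(pos))
  } else if (identical(placement, "interleaved")) {
    # spread through the batch at odd fractions (2i+1)/(2k+1), ending on a
    # centre run; reproduces the canonical 15-run worksheet layout with
    # centre runs at ordinal positions 6, 10 and 15
    pos <- floor(n_total * (2 * seq_len(k) + 1) / (2 * k + 1))
    stopifnot(length(unique(pos)) == k)
  } else if (identical(placement, "end")) {
    pos <- n0 + seq_len(k)
  } else {
    stop("unknown placement policy", call. = FALSE)
  }
  coded <- matrix(0L, n_total, ncol(design$coded))
  coded[setdiff(seq_len(n_total), pos), ] <- design$coded
  .new_design_matrix(coded, design$factors)
}

#' Decode a coded run into physical factor settings
#'
#' Maps coded levels to the physical values of each [factor_spec()]:
#' -1 to `low`, 0 to `centre`, +1 to `high`. Dummy factors pass the coded
#' value through unchanged.
#'
#' @param run Integer vector of coded levels in \{-1, 0, +1\}, or a pattern
#'   string such as `"+--+..."` (`"0"` for a centre run).
#' @param factors List of [factor_spec()] objects, one per design column.
#' @return Named numeric vector of physical values (names are factor names).
#' @examples
#' fs <- list(factor_spec("Metanol", "uL", 98, 100, 102),
#'            factor_spec("Dummy", is_dummy = TRUE))
#' decode_run(c(1L, -1L), fs)
#' @export
decode_run <- function(run, factors) {
  if (is.character(run)) run <- .pattern_to_levels(run, length(factors))
  run <- as.integer(run)
  if (length(run) != length(factors)) {
    stop(sprintf("run has %d levels for %d factors", length(run),
                 length(factors)), call. = FALSE)
  }
  if (!all(run %in% c(-1L, 0L, 1L))) {
    stop("coded levels must be -1, 0 or +1", call. = FALSE)
  }
  vals <- mapply(function(lev, fs) {
    if (fs$is_dummy) return(as.numeric(lev))
    switch(as.character(lev), `-1` = fs$low, `0` = fs$centre, `1` = fs$high)
  }, run, factors)
  names(vals) <- vapply(factors, `[[`, character(1), "name")
  vals
}

#' Encode physical factor settings back to coded levels
#'
#' Inverse of [decode_run()]: each physical value must equal one of the
#' factor's low/centre/high levels exactly.
#'
#' @param values Named or ordered numeric vector of physical values.
#' @param factors List of [factor_spec()] objects.
#' @return Integer vector of coded levels in \{-1, 0, +1\}.
#' @export
encode_run <- function(values, factors) {
  stopifnot(length(values) == length(factors))
  out <- mapply(function(v, fs) {
    lv <- c(fs$low, fs$centre, fs$high)
    i <- which(vapply(lv, function(l) isTRUE(all.equal(l, v)), logical(1)))
    if (length(i) != 1L) {
      stop(sprintf("value %s matches no level of factor '%s'",
                   format(v), fs$name), call. = FALSE)
    }
    c(-1L, 0L, 1L)[i]
  }, as.numeric(values), factors)
  as.integer(out)
}

#' Validate the screening properties of a design
#'
#' Checks, over the factorial runs only (centre runs carry no contrast
#' information), that every coded column is balanced (equal counts of -1 and
#' +1) and that every unordered pair of columns is orthogonal (zero dot
#' product). These are the properties that let a Plackett-Burman screen
#' estimate each main effect free of the others.
#'
#' @param design A `design_matrix`.
#' @return A `design_validation_report`: list with `balanced` (named logical
#'   per factor), `orthogonal` (logical matrix over factor pairs), `ok`
#'   (overall flag) and `messages`.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "design_matrix"))
  if (nrow(design$coded) == 0L) stop("design is empty", call. = FALSE)
  fac <- design$coded[!design$is_centre, , drop = FALSE]
  nm <- colnames(design$coded)
  messages <- character(0)
  if (nrow(fac) == 0L) {
    balanced <- setNames(rep(TRUE, length(nm)), nm)
    orthogonal <- matrix(TRUE, length(nm), length(nm), dimnames = list(nm, nm))
    messages <- "design contains only centre runs; screening properties are vacuous"
  } else {
    if (!all(fac %in% c(-1L, 1L))) {
      messages <- c(messages,
                    "factorial runs contain coded levels other than -1/+1")
    }
    balanced <- colSums(fac == 1L) == colSums(fac == -1L)
    names(balanced) <- nm
    G <- crossprod(fac)
    orthogonal <- G == 0L
    diag(orthogonal) <- TRUE
    dimnames(orthogonal) <- list(nm, nm)
    for (f in nm[!balanced]) {
      messages <- c(messages, sprintf("column '%s' is unbalanced", f))
    }
    bad <- which(!orthogonal & upper.tri(orthogonal), arr.ind = TRUE)
    for (i in seq_len(nrow(bad))) {
      messages <- c(messages,
                    sprintf("columns '%s' and '%s' are not orthogonal (dot product %d)",
                            nm[bad[i, 1L]], nm[bad[i, 2L]],
                            G[bad[i, 1L], bad[i, 2L]]))
    }
    if (design$n_factorial %% 4L != 0L) {
      messages <- c(messages, sprintf(
        "number of factorial runs (%d) is not a multiple of 4",
        design$n_factorial))
    }
  }
  structure(
    list(balanced = balanced, orthogonal = orthogonal,
         ok = all(balanced) && all(orthogonal) &&
           design$n_factorial %% 4L == 0L,
         messages = messages),
    class = "design_validation_report"
  )
}

#' @export
print.design_validation_report <- function(x, ...) {
  cat(sprintf("<design_validation_report> %s\n",
              if (x$ok) "PASS" else "FAIL"))
  for (m in x$messages) cat(" -", m, "\n")
  invisible(x)
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d runs (%d factorial + %d centre), %d factors\n",
              nrow(x$coded), x$n_factorial, x$n_centre, ncol(x$coded)))
  print(utils::head(cbind(run = x$run_ids, pattern = x$pattern,
                          as.data.frame(x$coded)), 15L))
  invisible(x)
}

#' Decode a whole design into a physical worksheet
#'
#' @param design A `design_matrix`.
#' @return Data frame: run id, pattern, one column per factor holding the
#'   physical value of each run.
#' @export
decode_design <- function(design) {
  stopifnot(inherits(design, "design_matrix"))
  phys <- t(apply(design$coded, 1L, decode_run, factors = design$factors))
  out <- data.frame(run = design$run_ids, pattern = design$pattern,
                    check.names = FALSE)
  cbind(out, as.data.frame(phys, check.names = FALSE))
}

#' Write / read a design matrix as CSV
#'
#' One row per run: `run`, `pattern`, then one column per factor. `coded =
#' TRUE` writes coded integers; otherwise the decoded physical worksheet.
#' Reading requires the factor specifications to recover coded levels from
#' physical values. Both the minus sign and the ASCII hyphen are accepted in
#' pattern strings on input; hyphens are emitted on output.
#'
#' @param design A `design_matrix`.
#' @param path File path.
#' @param coded Logical; write coded levels instead of physical values.
#' @return `write_design`: `path`, invisibly. `read_design`: a
#'   `design_matrix`.
#' @export
write_design <- function(design, path, coded = FALSE) {
  stopifnot(inherits(design, "design_matrix"))
  df <- if (coded) {
    cbind(data.frame(run = design$run_ids, pattern = design$pattern),
          as.data.frame(design$coded, check.names = FALSE))
  } else {
    decode_design(design)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param factors List of [factor_spec()]s describing the file's columns.
#' @rdname write_design
#' @export
read_design <- function(path, factors, coded = FALSE) {
  if (!file.exists(path)) stop(sprintf("design file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("run", "pattern")
  if (!all(need %in% names(df))) {
    stop("design CSV must have 'run' and 'pattern' columns", call. = FALSE)
  }
  nm <- vapply(factors, `[[`, character(1), "name")
  if (!all(nm %in% names(df))) {
    stop(sprintf("design CSV lacks factor columns: %s",
                 paste(setdiff(nm, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  vals <- as.matrix(df[, nm, drop = FALSE])
  coded_m <- if (coded) {
    storage.mode(vals) <- "integer"
    vals
  } else {
    t(apply(vals, 1L, encode_run, factors = factors))
  }
  d <- .new_design_matrix(coded_m, factors, run_ids = df$run)
  # cross-check patterns against numeric columns, row by row
  pat_in <- chartr("−", "-", df$pattern)
  mism <- which(pat_in != d$pattern)
  if (length(mism)) {
    stop(sprintf("pattern/level mismatch in rows: %s",
                 paste(df$run[mism], collapse = ", ")), call. = FALSE)
  }
  d
}

#' The packaged tumour-extraction robustness design
#'
#' Returns the 15-run Plackett-Burman worksheet used to robustness-test a
#' stepwise MTBE/methanol/water extraction: ten protocol factors (solvent
#' volumes, vortexing and centrifugation times, evaporation temperature,
#' reconstitution volume) plus one dummy factor, 12 factorial runs and 3
#' interleaved centre-point runs. Shipped as a plain CSV under
#' `inst/extdata/` together with the factor levels.
#'
#' Note: the `vortex1` column is labelled minutes in the source worksheet but
#' its levels (165/180/195) are plausibly seconds; the printed numbers and
#' unit are preserved as-is.
#'
#' @return A `design_matrix` with 15 runs and 11 factors.
#' @examples
#' d <- table1_design()
#' validate_design(d)$ok
#' @export
table1_design <- function() {
  fs <- table1_factors()
  read_design(system.file("extdata", "table1_design.csv", package = "pbmetab",
                          mustWork = TRUE), fs)
}

#' @rdname table1_design
#' @return `table1_factors`: the list of 11 [factor_spec()]s.
#' @export
table1_factors <- function() {
  read_factor_specs(system.file("extdata", "table1_factors.csv",
                                package = "pbmetab", mustWork = TRUE))
}

#' Read factor specifications from CSV
#'
#' Expects columns `name, units, low, centre, high, is_dummy`.
#'
#' @param path CSV path.
#' @return List of [factor_spec()]s.
#' @export
read_factor_specs <- function(path) {
  if (!file.exists(path)) stop(sprintf("factor spec file not found: %s",
                                       path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("name", "units", "low", "centre", "high", "is_dummy")
  if (!all(need %in% names(df))) {
    stop(sprintf("factor spec CSV lacks columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    if (isTRUE(as.logical(df$is_dummy[i]))) {
      factor_spec(df$name[i], is_dummy = TRUE)
    } else {
      factor_spec(df$name[i],
                  if (is.na(df$units[i])) "" else df$units[i],
                  df$low[i], df$centre[i], df$high[i])
    }
  })
}
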