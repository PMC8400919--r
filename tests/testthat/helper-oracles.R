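# Independent brute-force oracles used across the suite. These re-derive
# expected results with plain loops and base arithmetic, never by calling
# the implementation under test.

# Exhaustive balance / pairwise-orthogonality check of a coded matrix of
# factorial runs (rows all in {-1, +1}).
oracle_pb_properties <- function(fac) {
  balanced <- TRUE; orthogonal <- TRUE
  for (j in seq_len(ncol(fac))) {
    if (sum(fac[, j] == 1) != sum(fac[, j] == -1)) balanced <- FALSE
  }
  for (a in seq_len(ncol(fac) - 1)) {
    for (b in (a + 1):ncol(fac)) {
      if (sum(fac[, a] * fac[, b]) != 0) orthogonal <- FALSE
    }
  }
  list(balanced = balanced, orthogonal = orthogonal)
}

# Feature-quality cascade by per-feature enumeration on a plain abundance
# matrix (features x samples, NA = not detected).
oracle_cascade <- function(ab, blank_cols, rep_cols, cv_threshold = 20) {
  n_feat <- nrow(ab)
  in_blank <- post_blank <- present <- reproducible <- logical(n_feat)
  for (i in seq_len(n_feat)) {
    in_blank[i] <- FALSE
    for (j in blank_cols) if (!is.na(ab[i, j])) in_blank[i] <- TRUE
    post_blank[i] <- !in_blank[i]
    if (post_blank[i]) {
      ok <- TRUE
      for (j in rep_cols) if (is.na(ab[i, j])) ok <- FALSE
      present[i] <- ok
      if (ok) {
        x <- ab[i, rep_cols]
        m <- sum(x) / length(x)
        s <- sqrt(sum((x - m)^2) / (length(x) - 1))
        if (m != 0 && 100 * s / m < cv_threshold) reproducible[i] <- TRUE
      }
    }
  }
  list(post_blank = which(post_blank), present = which(present),
       reproducible = which(reproducible))
}

# Exclusive subset membership counts by looping over individual features.
oracle_exclusive_counts <- function(sets) {
  universe <- unique(unlist(sets))
  key_count <- new.env()
  for (feat in universe) {
    members <- names(sets)[vapply(sets, function(s) feat %in% s, logical(1))]
    key <- paste(members, collapse = "&")
    key_count[[key]] <- (if (is.null(key_count[[key]])) 0L
                         else key_count[[key]]) + 1L
  }
  out <- unlist(as.list(key_count))
  list(counts = out, union_size = length(universe))
}

# Least-squares projection of pooled factor effects on an orthogonal coded
# design: beta_f = sum_i x[i,f] * ybar_i / sum_i x[i,f]^2, with ybar the
# per-run mean of metabolite-centred log abundances.
oracle_ls_projection <- function(y, X) {
  yc <- sweep(y, 1L, rowMeans(y))
  ybar <- colMeans(yc)
  vapply(seq_len(ncol(X)), function(f) {
    sum(X[, f] * ybar) / sum(X[, f]^2)
  }, numeric(1))
}

# A small hand-buildable feature table: detections given as a features x
# samples logical matrix, abundances supplied explicitly.
make_table <- function(ab, roles, methods = NA, replicates = NA,
                       injections = seq_along(roles)) {
  n_feat <- nrow(ab); n_samp <- ncol(ab)
  feature_table(
    features = data.frame(feature_id = sprintf("f%02d", seq_len(n_feat)),
                          mz = 100 + seq_len(n_feat), rt = seq_len(n_feat)),
    samples = data.frame(sample_id = sprintf("s%02d", seq_len(n_samp)),
                         role = roles,
                         method = rep(methods, length.out = n_samp),
                         replicate = rep(replicates, length.out = n_samp),
                         design_run = NA_character_,
                         injection_order = injections),
    abundance = ab)
}
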