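make_pl <- function(id, mz, rt, ab, role = "study", method = NA,
                    replicate = NA, inj = 1L) {
  peak_list(id, role = role, method = method, replicate = replicate,
            injection_order = inj,
            peaks = data.frame(mz = mz, rt = rt, abundance = ab))
}

test_that("peak list and feature table I/O round-trip and reject bad input", {
  dir <- withr::local_tempdir()
  peaks <- data.frame(sample_id = rep(c("a", "b"), each = 2),
                      mz = c(100.1, 200.2, 100.1, 200.2),
                      rt = c(1, 2, 1, 2),
                      abundance = c(1000, 2000, 1100, 2100))
  meta <- data.frame(sample_id = c("a", "b"), role = "study",
                     method = "M", replicate = 1:2, design_run = NA,
                     injection_order = 1:2)
  pf <- file.path(dir, "peaks.csv"); mf <- file.path(dir, "meta.csv")
  write.csv(peaks, pf, row.names = FALSE)
  write.csv(meta, mf, row.names = FALSE)
  pls <- read_peak_lists(pf, mf)
  expect_length(pls, 2)
  expect_equal(pls[["a"]]$peaks$abundance, c(1000, 2000))

  # negative abundance rejected with the line number
  bad <- peaks; bad$abundance[3] <- -5
  write.csv(bad, pf, row.names = FALSE)
  expect_error(read_peak_lists(pf, mf), "line 4")

  # metadata missing a sample id names it
  write.csv(peaks, pf, row.names = FALSE)
  expect_error(read_peak_lists(pf, meta[1, ]), "b")

  # feature table CSV round-trip preserves values and missing cells
  tab <- make_table(matrix(c(1.25, NA, 3e6, 4.5, 5.5, NA), 3, 2),
                    roles = c("study", "study"), methods = "M",
                    replicates = 1:2)
  fp <- file.path(dir, "ft.csv")
  write_feature_table(tab, fp)
  back <- read_feature_table(fp)
  expect_equal(back$abundance, tab$abundance)
  expect_equal(back$features$mz, tab$features$mz)
})

test_that("noise filter drops strictly sub-threshold peaks only", {
  pl <- make_pl("s", c(100, 101, 102), c(1, 1, 1), c(150, 200, 5000))
  out <- noise_filter(pl)
  expect_equal(out$peaks$abundance, c(200, 5000))  # 200 is retained
  empty <- noise_filter(make_pl("e", numeric(0), numeric(0), numeric(0)))
  expect_equal(nrow(empty$peaks), 0L)
})

test_that("alignment honours the ppm and rt tolerances at their boundaries", {
  # 14.8 ppm apart, 0.10 min apart: inside both windows -> one feature
  a <- make_pl("a", 500.0000, 10.00, 1000)
  b <- make_pl("b", 500.0074, 10.10, 900)
  expect_equal(nrow(align_features(list(a, b))$features), 1L)
  # 16 ppm apart at equal rt -> two features
  b2 <- make_pl("b", 500.0080, 10.00, 900)
  expect_equal(nrow(align_features(list(a, b2))$features), 2L)
  # identical mz but 0.20 min apart -> two features
  b3 <- make_pl("b", 500.0000, 10.20, 900)
  expect_equal(nrow(align_features(list(a, b3))$features), 2L)
})

test_that("alignment recovers planted features exactly under half-tolerance jitter", {
  set.seed(11)
  k <- 40
  # seeds separated by much more than the full tolerance windows
  seeds_mz <- 100 + seq_len(k) * 5
  seeds_rt <- rep(seq(1, 20, length.out = 10), 4)
  pls <- lapply(1:3, function(s) {
    jmz <- seeds_mz * (1 + runif(k, -7, 7) * 1e-6)   # < 7.5 ppm
    jrt <- seeds_rt + runif(k, -0.07, 0.07)          # < 0.075 min
    make_pl(paste0("s", s), jmz, jrt, exp(rnorm(k, 10, 1)))
  })
  tab <- align_features(pls)
  expect_equal(nrow(tab$features), k)
  expect_true(all(!is.na(tab$abundance)))  # one peak per sample per feature
  # permutation invariance: sample order does not change the grouping
  tab_rev <- align_features(rev(pls))
  expect_equal(nrow(tab_rev$features), k)
  expect_equal(tab_rev$features$mz, tab$features$mz, tolerance = 1e-12)
})

test_that("one peak per sample per feature: a same-sample runner-up seeds a new feature", {
  pl <- make_pl("a", c(500.0000, 500.0030), c(10, 10), c(1000, 800))
  tab <- align_features(list(pl))
  expect_equal(nrow(tab$features), 2L)
})

test_that("noise filtering before alignment equals dropping noise-only features after", {
  set.seed(3)
  # well-separated seeds; sample 2 adds isolated sub-threshold peaks
  good <- make_pl("a", c(200, 300, 400), c(5, 10, 15), c(5000, 6000, 7000))
  noisy <- make_pl("b", c(200.0005, 300.0005, 600, 700), c(5, 10, 3, 4),
                   c(5100, 6100, 150, 120))
  t_filtered <- align_features(lapply(list(good, noisy), noise_filter))
  t_raw <- align_features(list(good, noisy))
  keep <- apply(t_raw$abundance, 1, function(r) any(r >= 200, na.rm = TRUE))
  expect_equal(nrow(t_filtered$features), sum(keep))
  expect_equal(t_filtered$features$mz, t_raw$features$mz[keep],
               tolerance = 1e-9)
})

test_that("adduct grouping ties co-eluting mass deltas and closes transitively", {
  tab <- make_table(matrix(1, 3, 1), roles = "study", methods = "M",
                    replicates = 1)
  tab$features$mz <- c(501.00728, 522.98922, 482.99671)
  tab$features$rt <- c(12, 12.05, 11.95)
  out <- annotate_adduct_groups(tab, "positive")
  # Na-H delta (21.98194) and water loss (18.01056) tie all three together
  expect_equal(length(unique(out$features$adduct_group)), 1L)
  # far-apart rt breaks the tie
  tab$features$rt <- c(12, 20, 11.95)
  out2 <- annotate_adduct_groups(tab, "positive")
  expect_equal(out2$features$adduct_group[1], out2$features$adduct_group[3])
  expect_false(out2$features$adduct_group[1] == out2$features$adduct_group[2])
  # a single feature is a singleton group
  single <- make_table(matrix(1, 1, 1), roles = "study", methods = "M",
                       replicates = 1)
  expect_equal(annotate_adduct_groups(single, "negative")$features$adduct_group,
               1L)
})
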