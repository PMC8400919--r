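# Build a robustness_dataset directly from a coded design and a matrix of
# log abundances (bypassing alignment) for focused model tests.
make_dataset <- function(y, design) {
  if (is.null(rownames(y))) rownames(y) <- sprintf("m%03d", seq_len(nrow(y)))
  structure(list(log_abundance = y,
                 design_coded = design$coded * 1,
                 metabolite_ids = rownames(y),
                 run_ids = design$run_ids,
                 factor_names = colnames(design$coded),
                 n_excluded = 0L, excluded_ids = character(0)),
            class = "robustness_dataset")
}

design15 <- add_centre_points(generate_pb_matrix(11), 3)

simulate_y <- function(design, m, beta, sigma, seed,
                       beta_m_sd = 0) {
  set.seed(seed)
  X <- design$coded
  alpha <- rnorm(m, 10, 1)
  t(vapply(seq_len(m), function(i) {
    b_i <- beta + rnorm(length(beta), 0, beta_m_sd)
    alpha[i] + as.vector(X %*% b_i) + rnorm(nrow(X), 0, sigma)
  }, numeric(nrow(X))))
}

test_that("dataset assembly log-transforms, orders by run and excludes incomplete features", {
  d <- add_centre_points(generate_pb_matrix(3), 1)
  ab <- matrix(c(100, 200, 300, 400, 500,
                 150, NA, 350, 450, 550), 2, 5, byrow = TRUE)
  tab <- make_table(ab, roles = rep("study", 5))
  tab$samples$design_run <- as.character(c(2, 1, 3, 4, 5))
  ds <- assemble_robustness_dataset(tab, d)
  expect_equal(ds$n_excluded, 1L)
  expect_equal(ds$excluded_ids, "f02")
  # columns reordered to design-run order; log(100) = 4.60517
  expect_equal(unname(ds$log_abundance[1, 1:2]), log(c(200, 100)),
               tolerance = 1e-12)
  expect_equal(unname(ds$log_abundance[1, 2]), 4.60517, tolerance = 1e-5)
  bad <- tab; bad$abundance[1, 1] <- 0
  expect_error(assemble_robustness_dataset(bad, d), "non-positive")
  unmapped <- tab; unmapped$samples$design_run[2] <- NA
  expect_error(assemble_robustness_dataset(unmapped, d), "not mapped")
})

test_that("pooled fit with flat priors equals the least-squares projection", {
  y <- simulate_y(design15, m = 30, beta = c(0.1, rep(0, 10)),
                  sigma = 0, seed = 1)
  ds <- make_dataset(y, design15)
  fit <- fit_pooled_model(ds, model_config(prior_scale_beta = Inf,
                                           prior_scale_sigma = Inf))
  # noiseless: the first factor's effect is recovered essentially exactly
  expect_equal(fit$coefficients$beta[1], 0.1, tolerance = 1e-9)
  expect_equal(fit$coefficients$beta[-1], rep(0, 10), tolerance = 1e-9)
  # noisy case matches the analytic projection oracle to 1e-6
  y2 <- simulate_y(design15, m = 50, beta = runif(11, -0.2, 0.2),
                   sigma = 0.3, seed = 2)
  ds2 <- make_dataset(y2, design15)
  fit2 <- fit_pooled_model(ds2, model_config(prior_scale_beta = Inf,
                                             prior_scale_sigma = Inf))
  expect_equal(fit2$coefficients$beta, oracle_ls_projection(y2, ds2$design_coded),
               tolerance = 1e-6)
})

test_that("weak priors barely perturb, strong priors shrink toward zero", {
  y <- simulate_y(design15, m = 40, beta = c(-0.15, rep(0, 10)),
                  sigma = 0.2, seed = 3)
  ds <- make_dataset(y, design15)
  flat <- fit_pooled_model(ds, model_config(prior_scale_beta = Inf,
                                            prior_scale_sigma = Inf))
  weak <- fit_pooled_model(ds, model_config())
  strong <- fit_pooled_model(ds, model_config(prior_scale_beta = 1e-3))
  expect_equal(weak$coefficients$beta, flat$coefficients$beta,
               tolerance = 1e-3)
  expect_lt(abs(strong$coefficients$beta[1]), abs(flat$coefficients$beta[1]))
})

test_that("duplicating every metabolite leaves betas unchanged and shrinks their sd", {
  y <- simulate_y(design15, m = 20, beta = c(0.05, rep(0, 10)),
                  sigma = 0.2, seed = 4)
  ds1 <- make_dataset(y, design15)
  ds2 <- make_dataset(rbind(y, y), design15)
  cfg <- model_config(prior_scale_beta = Inf, prior_scale_sigma = Inf)
  f1 <- fit_pooled_model(ds1, cfg)
  f2 <- fit_pooled_model(ds2, cfg)
  expect_equal(f2$coefficients$beta, f1$coefficients$beta, tolerance = 1e-9)
  expect_true(all(f2$coefficients$sd < f1$coefficients$sd))
})

test_that("centre points leave noiseless betas unchanged", {
  d12 <- generate_pb_matrix(11)
  beta <- c(0.1, -0.05, rep(0, 9))
  y12 <- simulate_y(d12, m = 10, beta = beta, sigma = 0, seed = 5)
  y15 <- simulate_y(design15, m = 10, beta = beta, sigma = 0, seed = 5)
  cfg <- model_config(prior_scale_beta = Inf, prior_scale_sigma = Inf)
  f12 <- fit_pooled_model(make_dataset(y12, d12), cfg)
  f15 <- fit_pooled_model(make_dataset(y15, design15), cfg)
  expect_equal(f12$coefficients$beta, beta, tolerance = 1e-9)
  expect_equal(f15$coefficients$beta, beta, tolerance = 1e-9)
})

test_that("the Gibbs sampler agrees with the analytic projection and is seed-deterministic", {
  y <- simulate_y(design15, m = 30, beta = c(0.1, rep(0, 10)),
                  sigma = 0.2, seed = 6)
  ds <- make_dataset(y, design15)
  cfg <- model_config(method = "gibbs", iter = 600, burn = 200, seed = 10,
                      prior_scale_beta = Inf)
  g1 <- fit_pooled_model(ds, cfg)
  g2 <- fit_pooled_model(ds, cfg)
  expect_identical(g1$coefficients$beta, g2$coefficients$beta)
  ls <- oracle_ls_projection(y, ds$design_coded)
  # posterior means sit within Monte Carlo error of the flat-prior solution
  expect_lt(max(abs(g1$coefficients$beta - ls)), 5e-3)
  expect_true(all(g1$coefficients$sd > 0))
})

test_that("null-factor coefficient coverage is calibrated near 95% at 2 sd", {
  hits <- 0L; total <- 0L
  for (s in 1:40) {
    y <- simulate_y(design15, m = 100, beta = rep(0, 11), sigma = 0.2,
                    seed = 100 + s)
    fit <- fit_pooled_model(make_dataset(y, design15),
                            model_config(prior_scale_beta = Inf,
                                         prior_scale_sigma = Inf))
    hits <- hits + sum(abs(fit$coefficients$beta) < 2 * fit$coefficients$sd)
    total <- total + 11L
  }
  coverage <- hits / total
  expect_gt(coverage, 0.90)
  expect_lt(coverage, 0.99)
})

test_that("the dummy factor behaves like the real null factors", {
  # under all-zero effects the dummy's estimate is statistically
  # indistinguishable from the real factors' null estimates
  z <- vapply(1:30, function(s) {
    y <- simulate_y(design15, m = 50, beta = rep(0, 11), sigma = 0.2,
                    seed = 200 + s)
    fit <- fit_pooled_model(make_dataset(y, design15),
                            model_config(prior_scale_beta = Inf,
                                         prior_scale_sigma = Inf))
    fit$coefficients$beta[11] / fit$coefficients$sd[11]
  }, numeric(1))
  expect_lt(abs(mean(z)), 2 / sqrt(30) * 2)   # mean z near 0
  expect_gt(sd(z), 0.6); expect_lt(sd(z), 1.5)  # unit-ish spread
})

test_that("per-metabolite fit recovers population beta and tau", {
  y <- simulate_y(design15, m = 200, beta = rep(0.1, 11), sigma = 0.2,
                  seed = 7, beta_m_sd = 0.05)
  ds <- make_dataset(y, design15)
  fit <- fit_per_metabolite_model(ds, model_config(
    variant = "per_metabolite", prior_scale_tau = Inf,
    prior_scale_sigma = Inf))
  co <- fit$coefficients
  # population coefficients: all factors share true value 0.1
  expect_true(all(abs(co$beta - 0.1) < 3 * co$sd))
  expect_lt(abs(mean(co$beta) - 0.1), 0.01)
  # spread estimates concentrate near the true tau = 0.05
  expect_lt(abs(mean(fit$tau$tau) - 0.05), 0.02)
  # maximum-likelihood variance components at 15 runs carry a known
  # downward bias on sigma; allow for it
  expect_gt(fit$sigma, 0.14); expect_lt(fit$sigma, 0.23)
  # per-metabolite coefficients shrink toward the population value
  expect_lt(sd(fit$beta_m[, 1]), 0.05 + 0.02)
  expect_gt(sd(fit$beta_m[, 1]), 0.01)
})

test_that("as tau is forced to zero the per-metabolite fit matches the pooled fit", {
  y <- simulate_y(design15, m = 40, beta = c(0.1, rep(0, 10)), sigma = 0.2,
                  seed = 8, beta_m_sd = 0.03)
  ds <- make_dataset(y, design15)
  pooled <- fit_pooled_model(ds, model_config(prior_scale_beta = Inf,
                                              prior_scale_sigma = Inf))
  pinned <- fit_per_metabolite_model(ds, model_config(
    variant = "per_metabolite", fix_tau = 1e-8, prior_scale_sigma = Inf))
  expect_equal(pinned$coefficients$beta, pooled$coefficients$beta,
               tolerance = 1e-6)
})

test_that("a shared response across metabolites drives tau toward zero", {
  # contrast a shared response (true tau = 0) with a heterogeneous one
  # (true tau = 0.05): the estimated spreads must separate cleanly, with
  # the shared-response taus down at the estimator's noise floor
  y0 <- simulate_y(design15, m = 60, beta = c(0.1, rep(0, 10)), sigma = 0.15,
                   seed = 9, beta_m_sd = 0)
  y5 <- simulate_y(design15, m = 60, beta = c(0.1, rep(0, 10)), sigma = 0.15,
                   seed = 9, beta_m_sd = 0.05)
  cfg <- model_config(variant = "per_metabolite")
  fit0 <- fit_per_metabolite_model(make_dataset(y0, design15), cfg)
  fit5 <- fit_per_metabolite_model(make_dataset(y5, design15), cfg)
  expect_lt(mean(fit0$tau$tau), 0.5 * mean(fit5$tau$tau))
  expect_lt(max(fit0$tau$tau), 0.15 / sqrt(12))  # below the noise floor
})

test_that("per-metabolite fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  y <- simulate_y(design15, m = 60, beta = rep(0.08, 11), sigma = 0.2,
                  seed = 12, beta_m_sd = 0.04)
  ds <- make_dataset(y, design15)
  fit <- fit_per_metabolite_model(ds, model_config(
    variant = "per_metabolite", prior_scale_tau = Inf,
    prior_scale_sigma = Inf))
  long <- data.frame(
    y = as.vector(t(y)),
    metab = factor(rep(seq_len(nrow(y)), each = ncol(y))))
  X <- ds$design_coded
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  long <- cbind(long, X[rep(seq_len(nrow(X)), nrow(y)), ])
  fml <- stats::as.formula(paste(
    "y ~", paste(colnames(X), collapse = "+"),
    "+ (1 +", paste(colnames(X), collapse = "+"), "|| metab)"))
  lfit <- lme4::lmer(fml, data = long, REML = FALSE,
                     control = lme4::lmerControl(calc.derivs = FALSE))
  expect_equal(unname(fit$coefficients$beta),
               unname(lme4::fixef(lfit)[-1]), tolerance = 0.01)
})

test_that("coefficients translate to percent changes", {
  expect_identical(interpret_coefficient(0.1), 10)
  expect_identical(interpret_coefficient(-0.15), -15)
  expect_identical(interpret_coefficient(0), 0)
  expect_equal(interpret_coefficient(c(0.02, -0.3)), c(2, -30))
})

test_that("QC drift slopes match the closed form and gate on the median", {
  # constant QC signal: zero slopes, batch passes
  ab <- matrix(1000, 4, 3)
  tab <- make_table(ab, roles = rep("qc", 3), injections = c(1, 5, 9))
  rep_ <- qc_drift_check(tab)
  expect_true(rep_$pass)
  expect_equal(rep_$slopes$slope, rep(0, 4))
  # exact 5% multiplicative growth per injection: slope ln(1.05) = 0.04879
  growth <- matrix(rep(1000 * 1.05^(c(1, 5, 9)), each = 4), 4, 3)
  tab2 <- make_table(growth, roles = rep("qc", 3), injections = c(1, 5, 9))
  rep2 <- qc_drift_check(tab2)
  expect_equal(rep2$slopes$slope, rep(log(1.05), 4), tolerance = 1e-12)
  expect_equal(rep2$median_abs_slope, 0.04879, tolerance = 1e-4)
  expect_false(rep2$pass)
  # fewer than 3 QC injections is an error
  tab3 <- make_table(matrix(1, 2, 2), roles = rep("qc", 2))
  expect_error(qc_drift_check(tab3), "at least 3")
})

test_that("degenerate designs and undersized datasets are rejected", {
  d <- generate_pb_matrix(3)
  y <- matrix(rnorm(8), 2, 4)
  const <- make_dataset(y, d)
  const$design_coded[, 2] <- 1
  expect_error(fit_pooled_model(const), "degenerate")
  one <- make_dataset(y[1, , drop = FALSE], d)
  expect_error(fit_pooled_model(one), "at least 2")
  expect_error(fit_per_metabolite_model(make_dataset(y, d)), "at least 3")
})
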