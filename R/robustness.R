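#' Assemble the log-abundance dataset for robustness modelling
#'
#' Restricts a feature table to the study samples of a Plackett-Burman
#' batch, maps each sample to its design run, natural-log transforms the
#' abundances and drops every feature with a missing value in any run
#' (fifteen runs cannot support a missingness model; the exclusion count is
#' reported). Rows of the design and columns of the log-abundance matrix are
#' ordered by design run.
#'
#' @param table A `feature_table`.
#' @param design A `design_matrix` whose run ids the samples map to.
#' @param run_map Named vector mapping `sample_id` to design run id;
#'   defaults to the `design_run` column of the table's sample metadata.
#' @return A `robustness_dataset`: list with `log_abundance` (metabolites x
#'   runs), `design_coded` (runs x factors), `metabolite_ids`, `run_ids`,
#'   `factor_names`, `n_excluded` and `excluded_ids`.
#' @export
assemble_robustness_dataset <- function(table, design, run_map = NULL) {
  stopifnot(inherits(table, "feature_table"),
            inherits(design, "design_matrix"))
  study <- table$samples$role == "study"
  sids <- table$samples$sample_id[study]
  if (is.null(run_map)) {
    run_map <- stats::setNames(table$samples$design_run[study], sids)
  }
  unmapped <- sids[!(sids %in% names(run_map)) |
                     is.na(run_map[sids]) | run_map[sids] == "NA"]
  if (length(unmapped)) {
    stop(sprintf("study sample(s) not mapped to a design run: %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  pos <- match(as.character(run_map[sids]), as.character(design$run_ids))
  if (anyNA(pos)) {
    stop(sprintf("sample(s) mapped to unknown design run: %s",
                 paste(sids[is.na(pos)], collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(pos)) {
    stop("two samples map to the same design run", call. = FALSE)
  }
  ord <- order(pos)
  sids <- sids[ord]; pos <- pos[ord]
  ab <- table$abundance[, match(sids, table$samples$sample_id),
                        drop = FALSE]
  if (any(!is.na(ab) & ab <= 0)) {
    stop("non-positive abundance: natural log undefined", call. = FALSE)
  }
  complete <- rowSums(is.na(ab)) == 0L
  excluded <- table$features$feature_id[!complete]
  y <- log(ab[complete, , drop = FALSE])
  rownames(y) <- table$features$feature_id[complete]
  structure(
    list(log_abundance = y,
         design_coded = design$coded[pos, , drop = FALSE] * 1,
         metabolite_ids = rownames(y),
         run_ids = design$run_ids[pos],
         factor_names = colnames(design$coded),
         n_excluded = length(excluded),
         excluded_ids = excluded),
    class = "robustness_dataset")
}

#' @export
print.robustness_dataset <- function(x, ...) {
  cat(sprintf("<robustness_dataset> %d metabolites x %d runs, %d factors (%d features excluded for missingness)\n",
              nrow(x$log_abundance), ncol(x$log_abundance),
              length(x$factor_names), x$n_excluded))
  invisible(x)
}

#' Model configuration for the robustness fits
#'
#' Weakly-informative zero-centred priors: Normal(0, `prior_scale_beta`^2) on
#' factor coefficients, half-Normal(`prior_scale_tau`) on the
#' between-metabolite coefficient spread, half-Normal(`prior_scale_sigma`) on
#' the residual sd; metabolite intercepts are unpenalized. `method = "map"`
#' gives the deterministic penalized-maximum fit (Laplace uncertainties);
#' `method = "gibbs"` draws from the full posterior with a blocked conjugate
#' Gibbs sampler (pooled variant only; the sampler replaces the half-Normal
#' on sigma with a vague inverse-gamma on sigma^2 to keep conjugacy). Set a
#' prior scale to `Inf` for a flat prior.
#'
#' @param variant `"pooled"` (one coefficient per factor shared by all
#'   metabolites) or `"per_metabolite"` (partial pooling:
#'   beta[m,f] ~ Normal(beta[f], tau[f])).
#' @param method `"map"` or `"gibbs"`.
#' @param prior_scale_beta,prior_scale_tau,prior_scale_sigma Positive prior
#'   scales (defaults 1).
#' @param iter,burn Gibbs iterations kept / discarded.
#' @param seed Integer seed for the sampler.
#' @param fix_tau Optional fixed value (or per-factor vector) for tau in the
#'   per-metabolite variant instead of estimating it; `fix_tau = 0`
#'   reproduces the pooled model.
#' @return A `model_config` list.
#' @export
model_config <- function(variant = c("pooled", "per_metabolite"),
                         method = c("map", "gibbs"),
                         prior_scale_beta = 1, prior_scale_tau = 1,
                         prior_scale_sigma = 1,
                         iter = 1000L, burn = 250L, seed = 1L,
                         fix_tau = NULL) {
  variant <- match.arg(variant)
  method <- match.arg(method)
  stopifnot(prior_scale_beta > 0, prior_scale_tau > 0, prior_scale_sigma > 0,
            iter > 0, burn >= 0)
  structure(list(variant = variant, method = method,
                 prior_scale_beta = prior_scale_beta,
                 prior_scale_tau = prior_scale_tau,
                 prior_scale_sigma = prior_scale_sigma,
                 iter = as.integer(iter), burn = as.integer(burn),
                 seed = as.integer(seed), fix_tau = fix_tau),
            class = "model_config")
}

.check_dataset <- function(dataset, min_metab = 2L) {
  stopifnot(inherits(dataset, "robustness_dataset"))
  y <- dataset$log_abundance
  X <- dataset$design_coded
  if (nrow(y) < min_metab) {
    stop(sprintf("need at least %d metabolites", min_metab), call. = FALSE)
  }
  const <- apply(X, 2L, function(col) length(unique(col)) < 2L)
  if (any(const)) {
    stop(sprintf("degenerate design: constant factor column(s): %s",
                 paste(colnames(X)[const], collapse = ", ")), call. = FALSE)
  }
  invisible(NULL)
}

# Penalized-maximum fit of the pooled model. With the design columns centred
# the intercepts decouple from the coefficients, so the joint mode is found
# by a ridge solve for beta plus a scalar update for sigma, iterated to
# convergence.
.fit_pooled_map <- function(y, X, s_beta, s_sigma) {
  m <- nrow(y); n <- ncol(y); f <- ncol(X)
  N <- m * n
  xbar <- colMeans(X)
  Xc <- sweep(X, 2L, xbar)
  ybar <- rowMeans(y)
  Yc <- sweep(y, 1L, ybar)              # m x n, centred per metabolite
  XtX <- crossprod(Xc)                  # f x f
  Xty <- crossprod(Xc, colSums(Yc))     # sums over metabolites
  sigma2 <- stats::var(as.vector(Yc)) + 1e-12
  beta <- rep(0, f)
  for (it in 1:200) {
    lambda <- if (is.finite(s_beta)) sigma2 / s_beta^2 else 0
    A <- m * XtX + diag(lambda, f)
    beta_new <- solve(A, Xty)
    rss <- sum((Yc - tcrossprod(rep(1, m), as.vector(Xc %*% beta_new)))^2)
    if (is.finite(s_sigma)) {
      s2 <- s_sigma^2
      sigma2_new <- (-N * s2 + sqrt(N^2 * s2^2 + 4 * rss * s2)) / 2
    } else {
      sigma2_new <- rss / N
    }
    done <- max(abs(beta_new - beta)) < 1e-12 &&
      abs(sigma2_new - sigma2) < 1e-14
    beta <- as.vector(beta_new); sigma2 <- sigma2_new
    if (done) break
  }
  lambda <- if (is.finite(s_beta)) sigma2 / s_beta^2 else 0
  A <- m * XtX + diag(lambda, f)
  beta_sd <- sqrt(diag(solve(A)) * sigma2)
  # intercepts on the original (uncentred) coding
  alpha <- ybar - as.vector(xbar %*% beta)
  alpha_sd <- rep(sqrt(sigma2 / n), m)
  list(beta = beta, beta_sd = beta_sd, alpha = alpha, alpha_sd = alpha_sd,
       sigma = sqrt(sigma2))
}

# Blocked conjugate Gibbs sampler for the pooled model: alpha | beta, sigma
# are independent normals per metabolite; beta | alpha, sigma is an f-variate
# normal; sigma^2 | rest is inverse-gamma (vague IG(0.01, 0.01) prior).
.fit_pooled_gibbs <- function(y, X, s_beta, iter, burn, seed) {
  set.seed(seed)
  m <- nrow(y); n <- ncol(y); f <- ncol(X)
  N <- m * n
  XtX <- crossprod(X)
  a0 <- 0.01; b0 <- 0.01
  beta <- rep(0, f)
  alpha <- rowMeans(y)
  sigma2 <- stats::var(as.vector(sweep(y, 1L, alpha)))
  keep_beta <- matrix(NA_real_, iter, f)
  keep_alpha <- matrix(NA_real_, iter, m)
  keep_sigma <- numeric(iter)
  prior_prec <- if (is.finite(s_beta)) 1 / s_beta^2 else 0
  for (t in seq_len(iter + burn)) {
    fit_run <- as.vector(X %*% beta)              # length n
    alpha <- stats::rnorm(m, rowMeans(sweep(y, 2L, fit_run)),
                          sqrt(sigma2 / n))
    R <- sweep(y, 1L, alpha)                      # m x n residuals sans X
    prec <- m * XtX / sigma2 + diag(prior_prec, f)
    ch <- chol(prec)
    mu <- backsolve(ch, forwardsolve(t(ch), crossprod(X, colSums(R)) / sigma2))
    beta <- as.vector(mu + backsolve(ch, stats::rnorm(f)))
    E <- R - tcrossprod(rep(1, m), as.vector(X %*% beta))
    rss <- sum(E^2)
    sigma2 <- 1 / stats::rgamma(1, a0 + N / 2, b0 + rss / 2)
    if (t > burn) {
      keep_beta[t - burn, ] <- beta
      keep_alpha[t - burn, ] <- alpha
      keep_sigma[t - burn] <- sqrt(sigma2)
    }
  }
  list(beta = colMeans(keep_beta), beta_sd = apply(keep_beta, 2L, stats::sd),
       alpha = colMeans(keep_alpha),
       alpha_sd = apply(keep_alpha, 2L, stats::sd),
       sigma = mean(keep_sigma), draws_beta = keep_beta)
}

#' Fit the pooled robustness model
#'
#' The simplified hierarchical model: `y[m,i] = alpha[m] + sum_f beta[f] *
#' x[i,f] + eps`, `eps ~ Normal(0, sigma)`, with one coefficient per factor
#' shared across all metabolites and one free intercept per metabolite. On
#' the natural-log scale a coefficient `b` means an average multiplicative
#' change of `exp(b)` in abundance per unit increase of the coded level —
#' about `100*b` percent for small `b` (see [interpret_coefficient()]).
#' With flat priors and an orthogonal design the estimates coincide with the
#' analytic least-squares projection.
#'
#' @param dataset A `robustness_dataset`.
#' @param config A [model_config()]; the `variant` field is ignored here.
#' @return An `effect_estimates`: list with `coefficients` (data frame
#'   `factor`, `beta`, `sd`), `intercepts` (data frame `metabolite`,
#'   `alpha`, `sd`), `sigma`, `variant`, `method`.
#' @export
fit_pooled_model <- function(dataset, config = model_config()) {
  .check_dataset(dataset, 2L)
  y <- dataset$log_abundance
  X <- dataset$design_coded
  fit <- if (config$method == "gibbs") {
    .fit_pooled_gibbs(y, X, config$prior_scale_beta, config$iter,
                      config$burn, config$seed)
  } else {
    .fit_pooled_map(y, X, config$prior_scale_beta, config$prior_scale_sigma)
  }
  structure(
    list(coefficients = data.frame(factor = dataset$factor_names,
                                   beta = fit$beta, sd = fit$beta_sd,
                                   row.names = NULL),
         intercepts = data.frame(metabolite = dataset$metabolite_ids,
                                 alpha = fit$alpha, sd = fit$alpha_sd,
                                 row.names = NULL),
         sigma = fit$sigma,
         variant = "pooled", method = config$method),
    class = "effect_estimates")
}

# Negative penalized profile log-likelihood of the per-metabolite model,
# marginalizing the metabolite-specific coefficient deviations analytically:
# y_m ~ N(alpha_m * 1 + X beta, X diag(tau^2) X' + sigma^2 I).
.pm_nll <- function(ltheta, y, X, s_tau, s_sigma, fix_tau = NULL) {
  f <- ncol(X); n <- ncol(y); m <- nrow(y)
  if (is.null(fix_tau)) {
    tau <- exp(ltheta[seq_len(f)])
    sigma <- exp(ltheta[f + 1L])
  } else {
    tau <- rep(fix_tau, length.out = f)
    sigma <- exp(ltheta[1L])
  }
  V <- X %*% (tau^2 * t(X)) + diag(sigma^2, n)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdet <- 2 * sum(log(diag(ch)))
  W <- chol2inv(ch)
  w1 <- W %*% rep(1, n)
  M <- W - tcrossprod(w1) / sum(w1)
  ybar <- colMeans(y)
  XtMX <- crossprod(X, M %*% X)
  beta <- tryCatch(solve(XtMX, crossprod(X, M %*% ybar)),
                   error = function(e) NULL)
  if (is.null(beta)) return(1e10)
  Z <- sweep(y, 2L, as.vector(X %*% beta))      # m x n
  Q <- sum((Z %*% M) * Z)
  nll <- 0.5 * (m * logdet + Q)
  if (is.finite(s_tau) && is.null(fix_tau)) nll <- nll + sum(tau^2) / (2 * s_tau^2)
  if (is.finite(s_sigma)) nll <- nll + sigma^2 / (2 * s_sigma^2)
  nll
}

#' Fit the per-metabolite (partial-pooling) robustness model
#'
#' Extends the pooled model with metabolite-specific coefficients partially
#' pooled toward the population values: `beta[m,f] ~ Normal(beta[f],
#' tau[f])`. The deviations are marginalized analytically (the model is a
#' linear mixed model with independent random slopes), the variance
#' parameters `tau` and `sigma` are estimated by penalized marginal maximum
#' likelihood with the intercepts and population coefficients profiled out
#' by generalized least squares, and the per-metabolite coefficients are
#' recovered as empirical-Bayes (BLUP) estimates. As `tau -> 0` the
#' population coefficients converge to the pooled model's.
#'
#' @param dataset A `robustness_dataset` with at least 3 metabolites.
#' @param config A [model_config()]; `fix_tau` pins tau instead of
#'   estimating it.
#' @return An `effect_estimates` with additionally `tau` (data frame
#'   `factor`, `tau`, `sd`) and `beta_m` (metabolites x factors matrix of
#'   per-metabolite coefficients).
#' @export
fit_per_metabolite_model <- function(dataset, config = model_config(
                                       variant = "per_metabolite")) {
  .check_dataset(dataset, 3L)
  y <- dataset$log_abundance
  X <- dataset$design_coded
  f <- ncol(X); n <- ncol(y); m <- nrow(y)
  s_tau <- config$prior_scale_tau
  s_sigma <- config$prior_scale_sigma
  fix_tau <- config$fix_tau
  if (is.null(fix_tau)) {
    init <- c(rep(log(0.05), f), log(stats::sd(as.vector(y)) / 2 + 1e-6))
    opt <- stats::optim(init, .pm_nll, y = y, X = X, s_tau = s_tau,
                        s_sigma = s_sigma, fix_tau = NULL,
                        method = "L-BFGS-B", lower = -12, upper = 6,
                        hessian = TRUE)
    tau <- exp(opt$par[seq_len(f)])
    sigma <- exp(opt$par[f + 1L])
    # delta method on the log scale; singular Hessians give NA sds
    sds <- tryCatch(sqrt(diag(solve(opt$hessian))),
                    error = function(e) rep(NA_real_, f + 1L))
    tau_sd <- tau * sds[seq_len(f)]
    sigma_sd <- sigma * sds[f + 1L]
  } else {
    opt <- stats::optimize(function(ls) .pm_nll(ls, y, X, s_tau, s_sigma,
                                                fix_tau = fix_tau),
                           interval = c(-12, 6))
    tau <- rep(fix_tau, length.out = f)
    sigma <- exp(opt$minimum)
    tau_sd <- rep(NA_real_, f); sigma_sd <- NA_real_
  }
  V <- X %*% (tau^2 * t(X)) + diag(sigma^2, n)
  W <- chol2inv(chol(V))
  w1 <- W %*% rep(1, n)
  M <- W - tcrossprod(w1) / sum(w1)
  XtMX <- crossprod(X, M %*% X)
  ybar <- colMeans(y)
  beta <- as.vector(solve(XtMX, crossprod(X, M %*% ybar)))
  beta_sd <- sqrt(diag(solve(XtMX)) / m)
  Z <- sweep(y, 2L, as.vector(X %*% beta))
  alpha <- as.vector(Z %*% w1) / sum(w1)
  alpha_sd <- rep(sqrt(1 / sum(w1)), m)
  # empirical-Bayes deviations: b_m = D X' V^-1 (y_m - alpha_m - X beta)
  R <- sweep(Z, 1L, alpha)                       # m x n residuals
  b <- R %*% W %*% X %*% diag(tau^2, f)          # m x f BLUPs
  beta_m <- sweep(b, 2L, beta, "+")
  colnames(beta_m) <- dataset$factor_names
  rownames(beta_m) <- dataset$metabolite_ids
  structure(
    list(coefficients = data.frame(factor = dataset$factor_names,
                                   beta = beta, sd = beta_sd,
                                   row.names = NULL),
         intercepts = data.frame(metabolite = dataset$metabolite_ids,
                                 alpha = alpha, sd = alpha_sd,
                                 row.names = NULL),
         tau = data.frame(factor = dataset$factor_names, tau = tau,
                          sd = tau_sd, row.names = NULL),
         sigma = sigma, sigma_sd = sigma_sd,
         beta_m = beta_m,
         variant = "per_metabolite", method = "map"),
    class = "effect_estimates")
}

#' @export
print.effect_estimates <- function(x, ...) {
  cat(sprintf("<effect_estimates> %s model (%s), sigma = %.4g\n",
              x$variant, x$method, x$sigma))
  df <- x$coefficients
  df$pct_change <- interpret_coefficient(df$beta)
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Interpret a log-scale coefficient as a percent change
#'
#' A coefficient `b` on natural-log abundance means each unit increase of
#' the coded factor level (e.g. 0 to +1) multiplies abundance by `exp(b)`
#' on average. For small coefficients this is approximately `100 * b`
#' percent — the conventional reading, returned here: 0.1 becomes +10%,
#' -0.15 becomes -15%. The exact multiplicative change is
#' `(exp(b) - 1) * 100` percent.
#'
#' @param beta Numeric coefficient(s) on the natural-log scale.
#' @return Percent change per unit coded-level increase (`100 * beta`).
#' @examples
#' interpret_coefficient(0.1)    # +10
#' interpret_coefficient(-0.15)  # -15
#' @export
interpret_coefficient <- function(beta) {
  100 * beta
}

#' Check QC-injection signal drift across a batch
#'
#' Repeated injections from one QC vial should give constant signals; a
#' systematic trend with injection order indicates instrument drift. For
#' each feature the least-squares slope of natural-log abundance against
#' injection order is computed; the batch fails when the median absolute
#' slope exceeds the threshold.
#'
#' @param table A `feature_table`; QC samples are those with role `"qc"`
#'   (or pass `qc_sample_ids`).
#' @param qc_sample_ids Optional explicit QC sample ids.
#' @param threshold Median absolute log-slope per injection above which the
#'   batch is flagged (default 0.01, i.e. about 1% signal change per
#'   injection).
#' @return A `qc_drift_report`: list with `slopes` (data frame `feature_id`,
#'   `slope`, `n_used`), `median_abs_slope`, `threshold`, `pass`.
#' @export
qc_drift_check <- function(table, qc_sample_ids = NULL, threshold = 0.01) {
  stopifnot(inherits(table, "feature_table"), threshold > 0)
  if (is.null(qc_sample_ids)) {
    qc_sample_ids <- table$samples$sample_id[table$samples$role == "qc"]
  }
  cols <- match(qc_sample_ids, table$samples$sample_id)
  if (anyNA(cols)) stop("unknown QC sample id(s)", call. = FALSE)
  if (length(cols) < 3L) {
    stop("QC drift check needs at least 3 QC injections", call. = FALSE)
  }
  ord <- table$samples$injection_order[cols]
  ab <- table$abundance[, cols, drop = FALSE]
  if (any(!is.na(ab) & ab <= 0)) {
    stop("non-positive QC abundance: natural log undefined", call. = FALSE)
  }
  slopes <- vapply(seq_len(nrow(ab)), function(i) {
    ok <- !is.na(ab[i, ])
    if (sum(ok) < 2L) return(NA_real_)
    x <- ord[ok]; z <- log(ab[i, ok])
    sum((x - mean(x)) * (z - mean(z))) / sum((x - mean(x))^2)
  }, numeric(1))
  med <- stats::median(abs(slopes), na.rm = TRUE)
  structure(
    list(slopes = data.frame(feature_id = table$features$feature_id,
                             slope = slopes,
                             n_used = rowSums(!is.na(ab)), row.names = NULL),
         median_abs_slope = med, threshold = threshold,
         pass = is.finite(med) && med <= threshold),
    class = "qc_drift_report")
}

#' @export
print.qc_drift_report <- function(x, ...) {
  cat(sprintf("<qc_drift_report> median |slope| = %.5f (threshold %.5f): %s\n",
              x$median_abs_slope, x$threshold,
              if (x$pass) "PASS" else "DRIFT FLAGGED"))
  invisible(x)
}

#' Serialize effect estimates
#'
#' CSV holds the per-factor coefficient table (factor, beta, sd, percent
#' change); JSON holds the full object including intercepts and, for the
#' per-metabolite variant, tau and the per-metabolite coefficients.
#'
#' @param estimates An `effect_estimates`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the coefficient data frame.
#' @export
write_effect_estimates <- function(estimates, csv_path = NULL,
                                   json_path = NULL) {
  stopifnot(inherits(estimates, "effect_estimates"))
  df <- estimates$coefficients
  df$pct_change <- interpret_coefficient(df$beta)
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    payload <- list(variant = estimates$variant, method = estimates$method,
                    sigma = estimates$sigma,
                    coefficients = df, intercepts = estimates$intercepts)
    if (!is.null(estimates$tau)) payload$tau <- estimates$tau
    if (!is.null(estimates$beta_m)) {
      payload$beta_m <- as.data.frame(estimates$beta_m)
      payload$beta_m <- cbind(metabolite = rownames(estimates$beta_m),
                              payload$beta_m)
    }
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
  }
  invisible(df)
}
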