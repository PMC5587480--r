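# Shared fixtures, memoised across test files (generated once per run).

the <- new.env(parent = emptyenv())

default_dataset <- function() {
  if (is.null(the$ds)) the$ds <- simulate_dataset(sim_config())
  the$ds
}

default_movements <- function() {
  if (is.null(the$mv)) {
    ds <- default_dataset()
    ret <- filter_encounters(ds$encounters,
                             filter_rules(years = sim_config()$years))
    mv <- build_movements(ret, ds$roster)
    the$thr <- estimate_thresholds(mv)
    the$mv <- classify_movements(mv, the$thr)
  }
  the$mv
}

default_thresholds <- function() {
  default_movements()
  the$thr
}

default_covariates <- function() {
  if (is.null(the$cov)) {
    ds <- default_dataset()
    the$cov <- build_covariate_table(default_movements(), ds$encounters,
                                     ds$weather, ds$burrows,
                                     compute_density_indices = FALSE)
  }
  the$cov
}

truth_model_terms <- function() {
  c(temporal_core_terms(), "sex", "sex:day", "fencing", "minor_roads",
    "tmax_32", "rain_32_cat", "tmax_32:rain_32_cat")
}

default_truth_fit <- function() {
  if (is.null(the$truth_fit))
    the$truth_fit <- fit_glmm(model_spec(truth_model_terms(), label = "truth"),
                              default_covariates())
  the$truth_fit
}

# Hand-written IRLS (Fisher scoring) for plain logistic regression: the
# independent oracle the mixed-model fit is checked against when the random
# effects are null.
irls_logistic <- function(X, y, offset = rep(0, length(y))) {
  b <- rep(0, ncol(X))
  for (it in 1:100) {
    eta <- drop(X %*% b) + offset
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    z <- (eta - offset) + (y - p) / w
    bn <- drop(solve(crossprod(X, w * X), crossprod(X, w * z)))
    if (max(abs(bn - b)) < 1e-12) { b <- bn; break }
    b <- bn
  }
  eta <- drop(X %*% b) + offset
  p <- 1 / (1 + exp(-eta))
  list(beta = b, ll = sum(y * log(p) + (1 - y) * log1p(-p)))
}

# Quick constructor of encounter tables for filter tests.
toy_encounters <- function(id = "A", dates, in_burrow = 1L,
                           x = NULL, y = NULL) {
  n <- length(dates)
  data.frame(tortoise_id = rep(id, length.out = n),
             date = as.Date(dates),
             x_m = if (is.null(x)) seq_len(n) * 1.0 else x,
             y_m = if (is.null(y)) rep(0, n) else y,
             in_burrow = rep(in_burrow, length.out = n),
             area = "release",
             stringsAsFactors = FALSE)
}

# Minimal fake fitted-model object for averaging/weighting tests.
fake_fit <- function(label, beta, se, bic_val, terms = names(beta)) {
  structure(list(
    spec = model_spec(terms, label = label),
    label = label,
    beta = beta, se = se,
    vcov = diag(se^2, nrow = length(se)),
    var_individual = 0, var_area = 0,
    LL = -bic_val / 2, K = length(beta) + 2L, n_obs = 100L,
    bic = bic_val, auc_conditional = 0.5, auc_marginal = 0.5,
    levels = list(), converged = TRUE), class = "acm_fit")
}

# Numeric minimum of the log1p-scale density of a two-component log-normal
# mixture (the estimand of the threshold estimator), in metres.
lognormal_mixture_min <- function(w_among, meanlog_w, sdlog_w,
                                  meanlog_a, sdlog_a) {
  f <- function(yy) {
    d <- expm1(yy)
    (1 - w_among) * stats::dlnorm(d, meanlog_w, sdlog_w) * exp(yy) +
      w_among * stats::dlnorm(d, meanlog_a, sdlog_a) * exp(yy)
  }
  expm1(stats::optimize(f, c(meanlog_w, meanlog_a + 1))$minimum)
}

# Minimal covariate-like table for direct GLMM tests (bypasses the full
# covariate build; only the referenced columns are needed).
glmm_toy_table <- function(n_ind = 50, n_per = 16, beta = c(-0.5, 0.8, -0.6),
                           sd_ind = 0, seed = 1) {
  withr::with_seed(seed, {
    n <- n_ind * n_per
    ind <- rep(sprintf("T%02d", seq_len(n_ind)), each = n_per)
    area <- rep(rep(c("a", "b", "c"), length.out = n_ind), each = n_per)
    x1 <- rnorm(n); x2 <- rnorm(n)
    b_ind <- rnorm(n_ind, 0, sd_ind)[match(ind, unique(ind))]
    off <- log(sample(5:8, n, TRUE))
    eta <- beta[1] + beta[2] * x1 + beta[3] * x2 + b_ind + off
    data.frame(tortoise_id = ind, area = area, x1 = x1, x2 = x2,
               offset_log_interval = off,
               is_acm = rbinom(n, 1, plogis(eta)),
               stringsAsFactors = FALSE)
  })
}

# First toy dataset (generated with null random effects) on which the
# variance MLE collapses to the boundary -- the regime where the mixed fit
# must reduce exactly to plain logistic regression.
zero_variance_case <- function(start_seed = 7) {
  for (s in start_seed + 0:14) {
    tab <- glmm_toy_table(n_ind = 50, n_per = 16, sd_ind = 0, seed = s)
    fit <- fit_glmm(model_spec(c("x1", "x2"), label = "oracle-check"), tab)
    if (isTRUE(fit$converged) && fit$var_individual < 1e-10 &&
        fit$var_area < 1e-10)
      return(list(tab = tab, fit = fit))
  }
  stop("no variance-collapsing draw found")
}
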