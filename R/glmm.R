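# Binomial (logit) mixed models with individual-within-area nested random
# intercepts and a log encounter-interval offset, fitted by Laplace
# approximation via lme4; BIC, AUC and collinearity diagnostics.

#' Specify a candidate model
#'
#' @param fixed_terms character vector of fixed-effect terms using covariate
#'   table column names (interactions as `"a:b"`); `character(0)` gives the
#'   intercept-only constant model. Non-constant candidates are expected to
#'   contain the temporal core ([temporal_core_terms()]).
#' @param label model label; derived from `group_tag` when omitted.
#' @param group_tag one of constant, temporal, individual, landscape,
#'   vegetation, weather, combination.
#' @return object of class `acm_model_spec`.
#' @export
model_spec <- function(fixed_terms, label = NULL,
                       group_tag = c("combination", "constant", "temporal",
                                     "individual", "landscape", "vegetation",
                                     "weather")) {
  group_tag <- match.arg(group_tag)
  fixed_terms <- unique(as.character(fixed_terms))
  if (is.null(label))
    label <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ")
             else "constant"
  structure(list(label = label, fixed_terms = fixed_terms,
                 group_tag = group_tag),
            class = "acm_model_spec")
}

#' @export
print.acm_model_spec <- function(x, ...) {
  cat(sprintf("Model spec [%s] %s\n  ~ %s + (1 | area/tortoise_id) + offset(log interval)\n",
              x$group_tag, x$label,
              if (length(x$fixed_terms)) paste(x$fixed_terms, collapse = " + ")
              else "1"))
  invisible(x)
}

#' Mandatory temporal core of every non-constant candidate
#'
#' Year main effect plus the cubic date polynomial and its interaction with
#' year.
#'
#' @return character vector of terms.
#' @export
temporal_core_terms <- function() {
  c("year", "day", "day2", "day3", "year:day", "year:day2", "year:day3")
}

# Columns whose raw scale is centered before entering the design (keeps
# temperature-by-rain interaction columns well-conditioned).
.center_map <- function(df) {
  for (cl in intersect(c("tmax_active", "tmax_32", "tmax_16"), names(df)))
    df[[cl]] <- df[[cl]] - .tmax_center
  df
}

#' Build the fixed design, response, grouping and offset for a model
#'
#' Categorical columns expand by treatment contrasts (reference levels:
#' first year, male, low rainfall). Temperature columns are centred at 33
#' degrees C before entering the design.
#'
#' @param spec an [model_spec()].
#' @param table an `acm_covariates` data.frame.
#' @return list with `y`, `X` (including intercept), `grouping`
#'   (`area`, `tortoise_id`), `offset`, `formula` (fixed part), `data`
#'   (transformed model data).
#' @export
build_design <- function(spec, table) {
  vars <- unique(unlist(strsplit(spec$fixed_terms, ":", fixed = TRUE)))
  miss <- setdiff(vars, names(table))
  if (length(miss))
    stop_acm("model '", spec$label, "' references missing columns: ",
             paste(miss, collapse = ", "))
  df <- .center_map(as.data.frame(table))
  rhs <- if (length(spec$fixed_terms))
    paste(spec$fixed_terms, collapse = " + ") else "1"
  f <- stats::as.formula(paste("~", rhs))
  X <- stats::model.matrix(f, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_acm("rank-deficient fixed design for '", spec$label,
             "'; aliased columns: ", paste(aliased, collapse = ", "))
  }
  list(y = df$is_acm, X = X,
       grouping = df[, c("area", "tortoise_id")],
       offset = df$offset_log_interval,
       formula = f, data = df)
}

#' Fit a binomial GLMM candidate
#'
#' Logit link, nested random intercepts for individuals within areas, and
#' the log encounter interval as an offset; the marginal likelihood is
#' maximized with the Laplace approximation (lme4, nloptwrap/BOBYQA
#' optimizer, fixed initialization — the fit is deterministic given the
#' data). `nAGQ = 0`
#' selects lme4's faster penalized-least-squares approximation, useful when
#' screening large candidate sets.
#'
#' @param spec an [model_spec()].
#' @param table an `acm_covariates` data.frame.
#' @param nAGQ integration setting for lme4 (1 = Laplace, 0 = fast PIRLS).
#' @param keep_fit keep the merMod object on the result.
#' @return object of class `acm_fit`: coefficients with SEs and covariance,
#'   variance components, `LL`, `K` (fixed effects + 2 variance components),
#'   `n_obs`, `bic`, conditional and marginal AUC, fitted probabilities and
#'   a convergence flag.
#' @export
fit_glmm <- function(spec, table, nAGQ = 1L, keep_fit = FALSE) {
  bd <- build_design(spec, table)
  if (anyNA(bd$y)) stop_acm("response contains NA; classify movements first")
  rhs <- if (length(spec$fixed_terms))
    paste(spec$fixed_terms, collapse = " + ") else "1"
  form <- stats::as.formula(paste(
    "is_acm ~", rhs,
    "+ (1 | area/tortoise_id) + offset(offset_log_interval)"))
  fit <- try(lme4::glmer(
    form, data = bd$data, family = stats::binomial(),
    nAGQ = nAGQ,
    control = lme4::glmerControl(optimizer = "nloptwrap",
                                 calc.derivs = FALSE)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    warning("model '", spec$label, "' failed to fit: ",
            attr(fit, "condition")$message)
    return(structure(list(spec = spec, converged = FALSE,
                          label = spec$label), class = "acm_fit"))
  }
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_individual <- vc$vcov[vc$grp == "tortoise_id:area"]
  var_area <- vc$vcov[vc$grp == "area"]
  LL <- as.numeric(stats::logLik(fit))
  n_obs <- stats::nobs(fit)
  K <- length(beta) + 2L
  eta_marg <- drop(bd$X %*% beta) + bd$offset
  p_cond <- stats::fitted(fit)
  p_marg <- stats::plogis(eta_marg)
  conv <- is.finite(LL) &&
    (is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0)
  out <- list(spec = spec, label = spec$label,
              beta = beta, se = sqrt(diag(V)), vcov = V,
              var_individual = var_individual, var_area = var_area,
              LL = LL, K = K, n_obs = n_obs,
              bic = bic(LL, K, n_obs),
              auc_conditional = auc(p_cond, bd$y),
              auc_marginal = auc(p_marg, bd$y),
              fitted_conditional = p_cond, fitted_marginal = p_marg,
              levels = lapply(Filter(is.factor, bd$data), levels),
              converged = conv)
  if (keep_fit) out$fit <- fit
  structure(out, class = "acm_fit")
}

#' @export
print.acm_fit <- function(x, ...) {
  if (!isTRUE(x$converged) && is.null(x$LL)) {
    cat("Unconverged fit:", x$label, "\n"); return(invisible(x))
  }
  cat(sprintf("Binomial GLMM '%s': K = %d, LL = %.1f, BIC = %.1f, AUC = %.2f (n = %d)\n",
              x$label, x$K, x$LL, x$bic, x$auc_conditional, x$n_obs))
  cat(sprintf("  random intercept variances: individual %.3f, area %.3f\n",
              x$var_individual, x$var_area))
  invisible(x)
}

#' Bayesian information criterion
#'
#' @param LL maximized log-likelihood.
#' @param K parameter count (fixed effects plus variance components).
#' @param n_obs number of observations.
#' @return `-2 * LL + K * log(n_obs)`.
#' @export
bic <- function(LL, K, n_obs) {
  stopifnot(n_obs >= 1)
  -2 * LL + K * log(n_obs)
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) formulation with ties averaged.
#'
#' @param scores predicted scores or probabilities.
#' @param response binary 0/1 response.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, response) {
  response <- as.integer(response)
  n1 <- sum(response == 1); n0 <- sum(response == 0)
  if (n1 == 0 || n0 == 0) stop_acm("AUC needs both response classes")
  r <- rank(scores)
  (sum(r[response == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Variance inflation factors of a fixed design
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing column j on the remaining
#' columns (intercept excluded from the diagnostics but kept as a
#' regressor). Perfectly collinear columns report `Inf`.
#'
#' @param X design matrix (with or without an intercept column) or an
#'   `acm_fit` design via [build_design()]'s `X`.
#' @return named numeric VIFs per non-intercept column.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  ic <- which(apply(X, 2, function(c) all(c == c[1])))
  keep <- setdiff(seq_len(ncol(X)), ic)
  if (length(keep) < 2L) stop_acm("need at least 2 non-intercept columns")
  out <- stats::setNames(numeric(length(keep)), colnames(X)[keep])
  for (jj in seq_along(keep)) {
    j <- keep[jj]
    yj <- X[, j]
    others <- cbind(1, X[, setdiff(keep, j), drop = FALSE])
    fit <- stats::lm.fit(others, yj)
    ssr <- sum(fit$residuals^2)
    sst <- sum((yj - mean(yj))^2)
    r2 <- if (sst == 0) 1 else 1 - ssr / sst
    out[jj] <- if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}
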