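# Two-stage candidate-set construction, BIC ranking and weights, model
# averaging with unconditional confidence intervals, and scenario prediction.

.all_subsets <- function(units) {
  n <- length(units)
  out <- list()
  for (m in 1:(2^n - 1)) {
    pick <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
    out[[length(out) + 1]] <- unlist(units[pick], use.names = FALSE)
  }
  out
}

#' Default first-stage candidate definitions
#'
#' For each non-temporal covariate group, the list of term sets (the
#' mandatory temporal core is added by [stage1_candidates()]). Weather and
#' NDVI covariates come in 16-day, 32-day and active-season windows; within
#' one model only a single window is used. Interactions are included only
#' where a seasonally dynamic relationship is hypothesized: sex-by-date,
#' NDVI-by-date, and temperature-by-rainfall.
#'
#' @return named list of groups, each a list of character term vectors.
#' @export
stage1_config <- function() {
  individual <- .all_subsets(list(
    sex = c("sex", "sex:day"),
    translocated = "translocated",
    mcl = "mcl_resid",
    density = "density_resid"))
  landscape <- .all_subsets(list(
    topography = c("slope", "roughness_resid"),
    wash = "wash_pct",
    roads = c("minor_roads", "major_roads"),
    fencing = "fencing",
    burrows = "burrows_resid"))
  vegetation <- list()
  for (w in c("ndvi_16", "ndvi_32")) {
    for (base in list(w, c(w, paste0(w, ":day")))) {
      vegetation[[length(vegetation) + 1]] <- base
      vegetation[[length(vegetation) + 1]] <- c(base, "shrub_pct")
    }
  }
  vegetation <- c(vegetation, list("shrub_pct", "ndvi_start_resid",
                                   "ndvi_active", c("ndvi_active", "shrub_pct")))
  weather <- list()
  wins <- list(`16` = c(tmax = "tmax_16", rain = "rain_16_cat"),
               `32` = c(tmax = "tmax_32", rain = "rain_32_cat"),
               active = c(tmax = "tmax_active", rain = "rain_active"))
  for (w in wins) {
    weather <- c(weather, list(
      w[["tmax"]], w[["rain"]], c(w[["tmax"]], w[["rain"]]),
      c(w[["tmax"]], w[["rain"]], paste0(w[["tmax"]], ":", w[["rain"]]))))
  }
  weather <- c(weather, list("rain_winter_resid"))
  list(individual = individual, landscape = landscape,
       vegetation = vegetation, weather = weather)
}

#' First-stage candidate models for one covariate group
#'
#' Every candidate contains the temporal core (year, cubic date, and their
#' interaction); group terms come from `config`.
#'
#' @param group one of `"individual"`, `"landscape"`, `"vegetation"`,
#'   `"weather"`.
#' @param config a [stage1_config()]-style list.
#' @return list of [model_spec()] objects.
#' @export
stage1_candidates <- function(group, config = stage1_config()) {
  sets <- config[[group]]
  if (is.null(sets) || !length(sets))
    stop_acm("empty or unknown covariate group: ", group)
  core <- temporal_core_terms()
  lapply(sets, function(terms)
    model_spec(c(core, terms),
               label = paste(terms, collapse = " + "),
               group_tag = group))
}

#' Select the best first-stage model of a group by BIC
#'
#' Fits every candidate; candidates that fail to converge are dropped with a
#' warning. Ties break by fewest parameters, then label order.
#'
#' @param candidates list of [model_spec()]s (see [stage1_candidates()]).
#' @param table an `acm_covariates` data.frame.
#' @param nAGQ passed to [fit_glmm()].
#' @return list with `best` (the winning `acm_fit`), and `ranking`
#'   (data.frame of label, K, LL, BIC sorted ascending).
#' @export
stage1_select <- function(candidates, table, nAGQ = 1L) {
  fits <- lapply(candidates, fit_glmm, table = table, nAGQ = nAGQ)
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!all(ok))
    warning(sum(!ok), " candidate(s) failed to converge and were dropped")
  fits <- fits[ok]
  if (!length(fits)) stop_acm("all first-stage candidates failed")
  rk <- data.frame(
    label = vapply(fits, `[[`, "", "label"),
    K = vapply(fits, `[[`, 0L, "K"),
    LL = vapply(fits, `[[`, 0, "LL"),
    BIC = vapply(fits, `[[`, 0, "bic"),
    stringsAsFactors = FALSE)
  o <- order(rk$BIC, rk$K, rk$label)
  list(best = fits[[o[1]]], ranking = rk[o, , drop = FALSE])
}

#' Second-stage (final) candidate set
#'
#' From the per-group first-stage winners: a constant (random effects only)
#' model, a temporal-only model, each winner singly, and every multi-group
#' union (terms deduplicated) — `2 + g + (2^g - 1 - g)` specs for `g`
#' winners, i.e. 17 for the four groups.
#'
#' @param winners named list mapping group tag to its winning group terms
#'   (character vector excluding the temporal core), or to `acm_fit` /
#'   `acm_model_spec` objects from stage 1.
#' @return list of [model_spec()]s.
#' @export
stage2_set <- function(winners) {
  if (is.null(names(winners)) || anyDuplicated(names(winners)))
    stop_acm("winners must be uniquely named by group")
  core <- temporal_core_terms()
  terms_of <- function(w) {
    if (inherits(w, "acm_fit")) w <- w$spec
    if (inherits(w, "acm_model_spec")) w <- w$fixed_terms
    setdiff(as.character(w), core)
  }
  gterms <- lapply(winners, terms_of)
  g <- length(gterms)
  specs <- list(
    model_spec(character(0), label = "Constant", group_tag = "constant"),
    model_spec(core, label = "Year and date", group_tag = "temporal"))
  cap <- function(s) paste0(toupper(substring(s, 1, 1)), substring(s, 2))
  for (m in 1:(2^g - 1)) {
    pick <- which(bitwAnd(m, 2^(seq_len(g) - 1)) > 0)
    nm <- names(gterms)[pick]
    lab <- paste(c(cap(nm[1]), nm[-1]), collapse = " + ")
    tag <- if (length(pick) == 1L) nm else "combination"
    specs[[length(specs) + 1]] <- model_spec(
      unique(c(core, unlist(gterms[pick], use.names = FALSE))),
      label = lab, group_tag = tag)
  }
  specs
}

#' Rank fitted candidates by BIC and compute model weights
#'
#' `delta_i = BIC_i - min BIC`; `w_i = exp(-delta_i / 2) / sum_j
#' exp(-delta_j / 2)`.
#'
#' @param fits list of `acm_fit` objects (unconverged fits are dropped with
#'   a warning), or a numeric vector of BIC (or delta-BIC) values.
#' @return object of class `acm_candidate_set`: a data.frame (label, K, LL,
#'   BIC, delta_bic, weight, AUC) sorted ascending by BIC, with the sorted
#'   fits attached as an attribute.
#' @export
rank_and_weight <- function(fits) {
  if (is.numeric(fits)) {
    delta <- fits - min(fits)
    w <- exp(-delta / 2); w <- w / sum(w)
    o <- order(delta)
    out <- data.frame(label = paste0("model", seq_along(fits))[o],
                      BIC = fits[o], delta_bic = delta[o], weight = w[o],
                      stringsAsFactors = FALSE)
    class(out) <- c("acm_candidate_set", "data.frame")
    return(out)
  }
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!all(ok))
    warning(sum(!ok), " fit(s) failed to converge and were dropped")
  fits <- fits[ok]
  if (!length(fits)) stop_acm("no converged fits to rank")
  df <- data.frame(
    label = vapply(fits, `[[`, "", "label"),
    K = vapply(fits, `[[`, 0L, "K"),
    LL = vapply(fits, `[[`, 0, "LL"),
    BIC = vapply(fits, `[[`, 0, "bic"),
    AUC = vapply(fits, `[[`, 0, "auc_conditional"),
    stringsAsFactors = FALSE)
  o <- order(df$BIC, df$K, df$label)
  df <- df[o, , drop = FALSE]
  df$delta_bic <- df$BIC - df$BIC[1]
  w <- exp(-df$delta_bic / 2)
  df$weight <- w / sum(w)
  df <- df[, c("label", "K", "LL", "BIC", "delta_bic", "weight", "AUC")]
  rownames(df) <- NULL
  structure(df, fits = fits[o], class = c("acm_candidate_set", "data.frame"))
}

#' @export
print.acm_candidate_set <- function(x, ...) {
  cat("Candidate set (BIC-ranked):\n")
  df <- as.data.frame(x)
  df$LL <- if ("LL" %in% names(df)) round(df$LL, 1) else NULL
  df$BIC <- round(df$BIC, 1); df$delta_bic <- round(df$delta_bic, 1)
  df$weight <- round(df$weight, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Model-averaged coefficients with unconditional confidence intervals
#'
#' Full averaging over the candidate set: a covariate absent from a model
#' contributes a coefficient of 0 with variance 0 (`conditional = TRUE`
#' averages only over models containing the term, renormalizing weights).
#' The unconditional SE combines within-model variance and between-model
#' spread: `se = sum_i w_i sqrt(var_i + (theta_i - theta_bar)^2)`. When the
#' top model's weight reaches `top_weight_rule` (default 0.95) averaging is
#' skipped and the top model's estimates are returned.
#'
#' @param candidate_set an `acm_candidate_set` built from `acm_fit`s.
#' @param conditional average only across models containing each term.
#' @param top_weight_rule weight above which the top model is used alone.
#' @param ci_level confidence level (normal quantile).
#' @return object of class `acm_averaged`: data.frame with `term`,
#'   `estimate`, `se_uncond`, `ci_lo`, `ci_hi`, `predictive` (CI excludes
#'   0); attributes `averaged` (logical) and `top_weight`.
#' @export
model_average <- function(candidate_set, conditional = FALSE,
                          top_weight_rule = 0.95, ci_level = 0.95) {
  fits <- attr(candidate_set, "fits")
  if (is.null(fits) || !length(fits)) stop_acm("empty candidate set")
  w <- candidate_set$weight
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  mk <- function(est, se) {
    data.frame(term = names(est), estimate = unname(est),
               se_uncond = unname(se),
               ci_lo = unname(est - z * se), ci_hi = unname(est + z * se),
               predictive = unname(est - z * se > 0 | est + z * se < 0),
               stringsAsFactors = FALSE)
  }
  if (w[1] >= top_weight_rule) {
    top <- fits[[1]]
    out <- mk(top$beta, top$se)
    return(structure(out, averaged = FALSE, top_weight = w[1],
                     levels = top$levels,
                     union_terms = top$spec$fixed_terms,
                     class = c("acm_averaged", "data.frame")))
  }
  terms <- unique(unlist(lapply(fits, function(f) names(f$beta))))
  est <- se <- stats::setNames(numeric(length(terms)), terms)
  for (tm in terms) {
    theta <- vapply(fits, function(f) f$beta[tm] %||% NA_real_, numeric(1))
    vv <- vapply(fits, function(f) (f$se[tm]^2) %||% NA_real_, numeric(1))
    theta[is.na(theta)] <- 0; vv[is.na(vv)] <- 0
    wi <- w
    if (conditional) {
      has <- vapply(fits, function(f) tm %in% names(f$beta), logical(1))
      wi <- ifelse(has, w, 0); wi <- wi / sum(wi)
    }
    tb <- sum(wi * theta)
    est[tm] <- tb
    se[tm] <- sum(wi * sqrt(vv + (theta - tb)^2))
  }
  union_terms <- unique(unlist(lapply(fits, function(f) f$spec$fixed_terms)))
  structure(mk(est, se), averaged = TRUE, top_weight = w[1],
            levels = fits[[1]]$levels, union_terms = union_terms,
            class = c("acm_averaged", "data.frame"))
}

#' @export
print.acm_averaged <- function(x, ...) {
  cat(sprintf("Model-averaged estimates (%s; top weight %.3f):\n",
              if (isTRUE(attr(x, "averaged"))) "full average"
              else "single supported model", attr(x, "top_weight")))
  df <- as.data.frame(x)
  df[, 2:5] <- round(df[, 2:5], 3)
  print(df, row.names = FALSE)
  invisible(x)
}

# Design rows for scenario prediction: factor coercion to training levels,
# temperature centering, then model.matrix on the requested terms.
.scenario_X <- function(terms, newdata, levels) {
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  miss <- setdiff(vars, names(newdata))
  if (length(miss))
    stop_acm("scenario table lacks columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(newdata)
  for (nm in intersect(names(levels), names(df)))
    df[[nm]] <- factor(df[[nm]], levels = levels[[nm]])
  df <- .center_map(df)
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  stats::model.matrix(stats::as.formula(paste("~", rhs)), df)
}

#' Predict among-center movement probability for scenarios
#'
#' Inverse-logit of the linear predictor at each scenario row (random
#' intercepts at zero), with delta-method confidence intervals. For a single
#' `acm_fit` the full coefficient covariance is used; for model-averaged
#' estimates the between-coefficient covariances are unavailable, so the
#' interval uses the diagonal (unconditional) variances.
#'
#' @param object an `acm_fit` or an `acm_averaged`.
#' @param newdata data.frame of scenarios supplying every model covariate;
#'   `offset_log_interval` defaults to `log(7)` when absent.
#' @param ci_level confidence level.
#' @return `newdata` with `eta`, `prob`, `prob_lo`, `prob_hi`.
#' @export
predict_scenarios <- function(object, newdata, ci_level = 0.95) {
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  off <- newdata$offset_log_interval %||% rep(log(7), nrow(newdata))
  if (inherits(object, "acm_fit")) {
    X <- .scenario_X(object$spec$fixed_terms, newdata, object$levels)
    X <- X[, names(object$beta), drop = FALSE]
    eta <- drop(X %*% object$beta) + off
    se <- sqrt(rowSums((X %*% object$vcov) * X))
  } else if (inherits(object, "acm_averaged")) {
    X <- .scenario_X(attr(object, "union_terms"), newdata,
                     attr(object, "levels"))
    b <- stats::setNames(object$estimate, object$term)
    s <- stats::setNames(object$se_uncond, object$term)
    X <- X[, object$term, drop = FALSE]
    eta <- drop(X %*% b) + off
    se <- sqrt(drop(X^2 %*% s^2))
  } else stop_acm("object must be an acm_fit or acm_averaged")
  out <- as.data.frame(newdata)
  out$eta <- eta
  out$prob <- stats::plogis(eta)
  out$prob_lo <- stats::plogis(eta - z * se)
  out$prob_hi <- stats::plogis(eta + z * se)
  out
}
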