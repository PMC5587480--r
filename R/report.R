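# Pipeline orchestration: simulate -> filter -> movements -> thresholds ->
# covariates -> two-stage selection -> averaging -> scenario predictions,
# driven by one config object, with logging, seed control and a manifest.

#' Pipeline configuration
#'
#' All randomness flows from the single root `seed`, split per stage; the
#' simulator's own seed is overridden by the pipeline.
#'
#' @param sim a [sim_config()].
#' @param filter a [filter_rules()]; defaults to the simulation years.
#' @param kde a [kde_spec()].
#' @param use_area a [use_area_spec()].
#' @param stage1 first-stage candidate definitions ([stage1_config()]).
#' @param groups covariate groups entered into stage 1.
#' @param n_boot Silverman-test bootstrap replicates.
#' @param alpha Silverman-test significance level.
#' @param nAGQ_stage1,nAGQ_stage2 lme4 integration settings per stage
#'   (1 = Laplace).
#' @param top_weight_rule model-averaging skip rule.
#' @param compute_density_indices compute the O(n^2) density indices.
#' @param seed integer root seed.
#' @return object of class `pipeline_config`. Unknown arguments are
#'   rejected.
#' @export
pipeline_config <- function(sim = sim_config(), filter = NULL,
                            kde = kde_spec(), use_area = use_area_spec(),
                            stage1 = stage1_config(),
                            groups = c("individual", "landscape",
                                       "vegetation", "weather"),
                            n_boot = 200L, alpha = 0.05,
                            nAGQ_stage1 = 1L, nAGQ_stage2 = 1L,
                            top_weight_rule = 0.95,
                            compute_density_indices = TRUE, seed = 1L, ...) {
  extra <- list(...)
  if (length(extra))
    stop_acm("unknown pipeline_config fields: ",
             paste(names(extra), collapse = ", "))
  if (is.null(filter)) filter <- filter_rules(years = sim$years)
  stopifnot(inherits(sim, "sim_config"), inherits(filter, "filter_rules"),
            inherits(kde, "kde_spec"), inherits(use_area, "use_area_spec"))
  if (!all(groups %in% names(stage1)))
    stop_acm("groups not present in stage-1 config: ",
             paste(setdiff(groups, names(stage1)), collapse = ", "))
  structure(list(sim = sim, filter = filter, kde = kde, use_area = use_area,
                 stage1 = stage1, groups = groups,
                 n_boot = as.integer(n_boot), alpha = alpha,
                 nAGQ_stage1 = nAGQ_stage1, nAGQ_stage2 = nAGQ_stage2,
                 top_weight_rule = top_weight_rule,
                 compute_density_indices = isTRUE(compute_density_indices),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage_names <- c("simulate", "filter", "movements", "thresholds",
                  "covariates", "selection", "report")

.log_line <- function(log_path, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
  message(line)
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a synthetic dataset generated from
#' `config$sim`, writing all intermediate artifacts (CSV tables, JSON
#' summaries, a plain-text log) plus a manifest into `out_dir`. Identical
#' config and seed give identical outputs. Any stage failure aborts with the
#' stage name.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created; must not contain a previous
#'   manifest unless `overwrite = TRUE`).
#' @param overwrite allow writing into a non-empty run directory.
#' @return invisible list with the main in-memory results (`summary`,
#'   `thresholds`, `candidate_set`, `averaged`, paths).
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dir.exists(out_dir) && file.exists(file.path(out_dir, "manifest.json")) &&
      !overwrite)
    stop_acm("run directory already contains a manifest; use overwrite = TRUE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  rows <- stats::setNames(rep(NA_integer_, length(.stage_names)), .stage_names)
  stage <- function(name, expr) {
    .log_line(log_path, "stage ", name, ": start")
    res <- tryCatch(expr, error = function(e)
      stop_acm("stage '", name, "' failed: ", conditionMessage(e)))
    .log_line(log_path, "stage ", name, ": done")
    res
  }

  # 1 simulate
  sim_cfg <- config$sim
  sim_cfg$rng_seed <- child_seed(config$seed, 1L)
  ds <- stage("simulate", simulate_dataset(sim_cfg))
  rows["simulate"] <- nrow(ds$encounters)
  .write_csv(ds$roster, file.path(out_dir, "roster.csv"))
  .write_csv(ds$encounters, file.path(out_dir, "encounters.csv"))
  .write_csv(ds$weather, file.path(out_dir, "weather.csv"))
  .write_csv(ds$burrows, file.path(out_dir, "burrows.csv"))
  export_truth(ds$truth, file.path(out_dir, "truth.json"))

  # 2 filter
  retained <- stage("filter", {
    r <- filter_encounters(ds$encounters, config$filter)
    if (nrow(r) == 0L)
      stop("no encounters retained; check the filter years/months against the data")
    r
  })
  rows["filter"] <- nrow(retained)

  # 3 movements
  movements <- stage("movements", build_movements(
    retained, ds$roster, config$filter$interval_min, config$filter$interval_max))
  rows["movements"] <- nrow(movements)
  dsum <- summarize_distances(movements)
  jsonlite::write_json(dsum, file.path(out_dir, "distance_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  # 4 thresholds
  modes_out <- stage("thresholds", {
    sil <- lapply(split(movements$distance_m, movements$sex), function(d)
      silverman_test(log1p(d), k = 1L, n_boot = config$n_boot,
                     seed = child_seed(config$seed, 4L), spec = config$kde))
    thr <- estimate_thresholds(movements, spec = config$kde)
    list(silverman = sil, thresholds = thr)
  })
  movements <- classify_movements(movements, modes_out$thresholds)
  .write_csv(movements, file.path(out_dir, "movements.csv"))
  thr_json <- lapply(names(modes_out$thresholds), function(s) {
    t <- modes_out$thresholds[[s]]
    list(sex_class = s, threshold_m = t$threshold_m,
         mode_locations_m = t$mode_locations_m,
         bandwidth = t$bandwidth, h_crit1 = t$h_crit1,
         silverman_p = modes_out$silverman[[s]]$p_value,
         silverman_h_crit = modes_out$silverman[[s]]$h_crit,
         n = modes_out$silverman[[s]]$n)
  })
  jsonlite::write_json(thr_json, file.path(out_dir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA)
  grids <- do.call(rbind, lapply(names(modes_out$thresholds), function(s) {
    t <- modes_out$thresholds[[s]]
    kd <- kde_density(log1p(movements$distance_m[movements$sex == s]),
                      t$bandwidth, config$kde)
    data.frame(sex = s, distance_m = expm1(kd$x), density = kd$y)
  }))
  .write_csv(grids, file.path(out_dir, "density_grids.csv"))
  rows["thresholds"] <- length(thr_json)

  # 5 covariates
  covars <- stage("covariates", build_covariate_table(
    movements, ds$encounters, ds$weather, ds$burrows, config$use_area,
    compute_density_indices = config$compute_density_indices))
  rows["covariates"] <- nrow(covars)
  .write_csv(covars, file.path(out_dir, "covariates.csv"))

  # 6 two-stage selection
  sel <- stage("selection", {
    s1cfg <- config$stage1
    if (!config$compute_density_indices) {
      # the index columns are identically zero in this mode; drop their terms
      s1cfg <- lapply(s1cfg, function(sets) {
        sets <- lapply(sets, setdiff, y = c("density_resid", "burrows_resid"))
        unique(Filter(length, sets))
      })
    }
    winners <- list()
    rankings <- list()
    for (g in config$groups) {
      s1 <- stage1_select(stage1_candidates(g, s1cfg), covars,
                          nAGQ = config$nAGQ_stage1)
      winners[[g]] <- s1$best
      rankings[[g]] <- s1$ranking
    }
    specs2 <- stage2_set(winners)
    fits2 <- lapply(specs2, fit_glmm, table = covars,
                    nAGQ = config$nAGQ_stage2)
    list(winners = winners, rankings = rankings,
         candidate_set = rank_and_weight(fits2))
  })
  cs <- sel$candidate_set
  rows["selection"] <- nrow(cs)
  tab2 <- as.data.frame(cs)
  .write_csv(tab2, file.path(out_dir, "candidate_models.csv"))
  for (g in names(sel$rankings))
    .write_csv(sel$rankings[[g]],
               file.path(out_dir, paste0("stage1_", g, ".csv")))

  # 7 averaging, scenarios, summary, manifest
  report <- stage("report", {
    avg <- model_average(cs, top_weight_rule = config$top_weight_rule)
    .write_csv(as.data.frame(avg), file.path(out_dir, "averaged_effects.csv"))
    ref <- .reference_scenario(covars)
    scen <- rbind(transform(ref, fencing = 0, scenario = "fence_absent"),
                  transform(ref, fencing = 1, scenario = "fence_present"),
                  transform(ref, minor_roads = 0, scenario = "road_absent"),
                  transform(ref, minor_roads = 1, scenario = "road_present"))
    pred <- predict_scenarios(avg, scen)
    .write_csv(pred[, c("scenario", "fencing", "minor_roads", "eta",
                        "prob", "prob_lo", "prob_hi")],
               file.path(out_dir, "scenario_predictions.csv"))
    summary <- list(
      n_encounters = nrow(ds$encounters),
      n_retained = nrow(retained),
      n_movements = nrow(movements),
      n_individuals = dsum$n_individuals,
      median_distance_m = dsum$median_m,
      among_fraction = mean(movements$is_acm),
      thresholds_m = stats::setNames(
        vapply(modes_out$thresholds, `[[`, 0, "threshold_m"),
        names(modes_out$thresholds)),
      best_model = cs$label[1],
      best_model_bic = cs$BIC[1],
      best_model_weight = cs$weight[1],
      best_model_auc = cs$AUC[1],
      averaging_applied = isTRUE(attr(avg, "averaged")),
      seed = config$seed)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(avg = avg, pred = pred, summary = summary)
  })
  rows["report"] <- 1L

  files <- setdiff(list.files(out_dir), c("manifest.json", "run.log"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("acmove")),
    seed = config$seed,
    stages = data.frame(stage = .stage_names, rows = as.integer(rows),
                        complete = TRUE),
    files = data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(out_dir, files)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  .log_line(log_path, "run complete: ", nrow(movements), " movements, ",
            "best model '", cs$label[1], "'")
  invisible(list(summary = report$summary, thresholds = modes_out$thresholds,
                 candidate_set = cs, averaged = report$avg,
                 out_dir = out_dir))
}

# A covariate-table reference row for scenario prediction: numeric columns
# at their mean, factors at their reference level, presence flags off,
# 7-day interval.
.reference_scenario <- function(covars) {
  ref <- as.data.frame(covars)[1, , drop = FALSE]
  for (nm in names(ref)) {
    col <- covars[[nm]]
    if (is.factor(col)) ref[[nm]] <- factor(levels(col)[1], levels(col))
    else if (is.numeric(col)) ref[[nm]] <- mean(col)
  }
  ref$fencing <- 0; ref$minor_roads <- 0; ref$major_roads <- 0
  ref$translocated <- 0
  ref$offset_log_interval <- log(7)
  ref
}

#' Summarize a completed run directory
#'
#' Verifies the manifest (every stage complete, artifact checksums intact)
#' and assembles a short human-readable report: counts, per-sex thresholds,
#' the candidate ranking head, and the averaged-effect headline.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return character vector of report lines (also printed).
#' @export
summarize_run <- function(run_dir) {
  man_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(man_path)) stop_acm("incomplete run: no manifest found")
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  if (!all(man$stages$complete) ||
      !setequal(man$stages$stage, .stage_names))
    stop_acm("incomplete run: not all stages completed")
  cur <- unname(tools::md5sum(file.path(run_dir, man$files$file)))
  if (anyNA(cur) || any(cur != man$files$md5))
    stop_acm("integrity error: run artifacts do not match the manifest")
  summ <- jsonlite::read_json(file.path(run_dir, "summary.json"),
                              simplifyVector = TRUE)
  thr <- jsonlite::read_json(file.path(run_dir, "thresholds.json"),
                             simplifyVector = TRUE)
  tab2 <- utils::read.csv(file.path(run_dir, "candidate_models.csv"))
  lines <- c(
    sprintf("Run %s (seed %d)", run_dir, summ$seed),
    sprintf("Movements: %d among %d individuals (%d encounters retained of %d)",
            summ$n_movements, summ$n_individuals, summ$n_retained,
            summ$n_encounters),
    sprintf("Median distance %.1f m; among-center fraction %.3f",
            summ$median_distance_m, summ$among_fraction),
    "Thresholds (m):",
    sprintf("  %s: %.1f (Silverman p = %.3g)", thr$sex_class, thr$threshold_m,
            thr$silverman_p),
    "Second-stage ranking (top 5):",
    sprintf("  %-45s BIC %.1f  dBIC %5.1f  w %.3f", utils::head(tab2$label, 5),
            utils::head(tab2$BIC, 5), utils::head(tab2$delta_bic, 5),
            utils::head(tab2$weight, 5)),
    if (isTRUE(summ$averaging_applied))
      "Coefficients were model-averaged across the second-stage set."
    else
      sprintf("Top model weight %.3f >= rule: single-model estimates used.",
              summ$best_model_weight),
    sprintf("Best model: %s (AUC %.2f)", summ$best_model, summ$best_model_auc))
  cat(lines, sep = "\n")
  invisible(lines)
}
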