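# Synthetic encounter-history generator.
#
# Emulates the statistical structure the downstream analysis assumes: three
# monitoring areas, three sex categories, weekly (5-8 day) encounters over
# May-October active seasons, a bimodal step-length distribution per sex class
# (log-normal within/among mixtures), covariate-driven among-center movement
# probability on the logit scale with nested random intercepts, and area-level
# daily weather/greenness series.

#' Default "truth" coefficients for the synthetic movement-state model
#'
#' Named log-odds coefficients on the scale of the fitted design matrix
#' (treatment contrasts; reference levels: first year, male, low rainfall).
#' Signs follow the directions the analysis is designed to detect: a positive
#' barrier-fence effect, a negative minor-road effect, a negative maximum
#' temperature effect under low rainfall that is relaxed by the
#' temperature-by-rain interaction, cubic date seasonality interacting with
#' year and sex, and null vegetation effects. Temperature enters centered at
#' 33 degrees C; day enters centered/scaled via [scale_day()].
#'
#' @param years integer vector of calendar years the simulation covers.
#' @return named numeric vector of coefficients.
#' @export
default_beta_truth <- function(years = 2013:2015) {
  years <- sort(unique(as.integer(years)))
  b <- c("(Intercept)" = -3.0,
         day = 0.25, day2 = -0.15, day3 = 0.08,
         sexfemale = -0.4, sexsubadult = -1.0,
         "day:sexfemale" = -0.10, "day:sexsubadult" = -0.15,
         fencing = 0.5, minor_roads = -0.5,
         tmax_32 = -0.08,
         rain_32_catmedium = 0.4, rain_32_cathigh = 0.7,
         "tmax_32:rain_32_catmedium" = 0.06,
         "tmax_32:rain_32_cathigh" = 0.09)
  yr_main <- c(0.3, -0.2, 0.15)
  yr_day <- c(0.10, -0.10, 0.05)
  yr_day2 <- c(-0.08, 0.06, -0.05)
  yr_day3 <- c(0.05, -0.04, 0.03)
  extra <- years[-1]
  for (i in seq_along(extra)) {
    yr <- extra[i]
    b[paste0("year", yr)] <- yr_main[(i - 1) %% 3 + 1]
    b[paste0("year", yr, ":day")] <- yr_day[(i - 1) %% 3 + 1]
    b[paste0("year", yr, ":day2")] <- yr_day2[(i - 1) %% 3 + 1]
    b[paste0("year", yr, ":day3")] <- yr_day3[(i - 1) %% 3 + 1]
  }
  b
}

#' Configuration for the synthetic telemetry generator
#'
#' @param n_individuals_per_area named integer vector, individuals per
#'   monitoring area; names become area labels.
#' @param sex_proportions 3-vector (male/female/subadult) summing to 1.
#' @param years calendar years simulated.
#' @param season_days active-season day-of-year interval (default May 1 to
#'   Oct 31).
#' @param encounter_interval_days inclusive range the regular re-encounter
#'   interval is drawn from.
#' @param gap_probability probability an interval is instead drawn from
#'   `gap_interval_days` (an out-of-range monitoring gap).
#' @param gap_interval_days inclusive range for gap intervals.
#' @param within_distance_params,among_distance_params per-sex-class
#'   log-normal location/scale (`meanlog`, `sdlog`) for step lengths, metres.
#' @param beta_truth named coefficient vector on the logit scale (see
#'   [default_beta_truth()]).
#' @param re_sd_individual,re_sd_area standard deviations of the nested
#'   random intercepts.
#' @param p_out_of_burrow probability an encounter is flagged outside a
#'   burrow.
#' @param p_fence named per-area probability that a newly occupied activity
#'   center lies near barrier fencing.
#' @param p_minor_road,p_major_road probabilities a newly occupied activity
#'   center lies near a minor (dirt) or major (paved) road.
#' @param p_translocated_release probability a release-area (first area)
#'   individual carries the translocated flag.
#' @param rng_seed integer seed; all generator output is deterministic given
#'   the seed and configuration.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_individuals_per_area = c(release = 54, control_west = 36,
                                                  control_east = 12),
                       sex_proportions = c(male = 0.50, female = 0.42,
                                           subadult = 0.08),
                       years = 2013:2015,
                       season_days = c(121L, 304L),
                       encounter_interval_days = c(5L, 8L),
                       gap_probability = 0.05,
                       gap_interval_days = c(9L, 14L),
                       within_distance_params = list(
                         male = c(meanlog = log(5.0), sdlog = 0.50),
                         female = c(meanlog = log(4.5), sdlog = 0.50),
                         subadult = c(meanlog = log(3.0), sdlog = 0.50)),
                       among_distance_params = list(
                         male = c(meanlog = log(250), sdlog = 0.90),
                         female = c(meanlog = log(200), sdlog = 0.90),
                         subadult = c(meanlog = log(110), sdlog = 0.90)),
                       beta_truth = default_beta_truth(years),
                       re_sd_individual = 0.45,
                       re_sd_area = 0.15,
                       p_out_of_burrow = 0.15,
                       p_fence = NULL,
                       p_minor_road = 0.15,
                       p_major_road = 0.015,
                       p_translocated_release = 0.30,
                       rng_seed = 1L) {
  if (is.null(names(n_individuals_per_area)))
    names(n_individuals_per_area) <- paste0("area", seq_along(n_individuals_per_area))
  if (is.null(p_fence)) {
    p_fence <- stats::setNames(rep(0, length(n_individuals_per_area)),
                               names(n_individuals_per_area))
    p_fence[1] <- 0.30
  }
  cfg <- structure(list(
    n_individuals_per_area = n_individuals_per_area,
    sex_proportions = sex_proportions,
    years = sort(unique(as.integer(years))),
    season_days = as.integer(season_days),
    encounter_interval_days = as.integer(encounter_interval_days),
    gap_probability = gap_probability,
    gap_interval_days = as.integer(gap_interval_days),
    within_distance_params = within_distance_params,
    among_distance_params = among_distance_params,
    beta_truth = beta_truth,
    re_sd_individual = re_sd_individual,
    re_sd_area = re_sd_area,
    p_out_of_burrow = p_out_of_burrow,
    p_fence = p_fence,
    p_minor_road = p_minor_road,
    p_major_road = p_major_road,
    p_translocated_release = p_translocated_release,
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  sexes <- c("male", "female", "subadult")
  if (length(cfg$sex_proportions) != 3L ||
      abs(sum(cfg$sex_proportions) - 1) > 1e-9 ||
      any(cfg$sex_proportions < 0))
    stop_acm("configuration error: sex_proportions must be a nonnegative ",
             "3-vector summing to 1")
  if (is.null(names(cfg$sex_proportions)))
    names(cfg$sex_proportions) <- sexes
  if (any(cfg$n_individuals_per_area < 0))
    stop_acm("configuration error: negative individuals per area")
  iv <- cfg$encounter_interval_days
  if (iv[1] < 1L || iv[2] > 14L || iv[1] > iv[2])
    stop_acm("configuration error: encounter interval range must lie in [1, 14]")
  for (s in sexes) {
    w <- cfg$within_distance_params[[s]]
    a <- cfg$among_distance_params[[s]]
    if (is.null(w) || is.null(a))
      stop_acm("configuration error: missing distance parameters for ", s)
    if (w[["sdlog"]] <= 0 || a[["sdlog"]] <= 0)
      stop_acm("configuration error: distance scale parameters must be > 0")
    if (exp(a[["meanlog"]]) <= exp(w[["meanlog"]]))
      stop_acm("configuration error: among-center median distance must exceed ",
               "within-center median for ", s)
  }
  if (cfg$re_sd_individual < 0 || cfg$re_sd_area < 0)
    stop_acm("configuration error: random-intercept SDs must be >= 0")
  if (!setequal(names(cfg$p_fence), names(cfg$n_individuals_per_area)))
    stop_acm("configuration error: p_fence must be named by area")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic telemetry configuration\n")
  cat("  areas:", paste(sprintf("%s (%d)", names(x$n_individuals_per_area),
                                x$n_individuals_per_area), collapse = ", "), "\n")
  cat("  years:", paste(x$years, collapse = ", "),
      sprintf(" season doy %d-%d\n", x$season_days[1], x$season_days[2]))
  cat(sprintf("  encounter interval %d-%d d (gap prob %.2f), seed %d\n",
              x$encounter_interval_days[1], x$encounter_interval_days[2],
              x$gap_probability, x$rng_seed))
  invisible(x)
}

#' Simulate a tortoise roster
#'
#' Draws one row per monitored individual: id, sex class, monitoring area,
#' translocation flag, and midline carapace length (MCL, cm).
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `tortoise_id`, `sex`, `area`,
#'   `translocated`, `mcl_cm`.
#' @export
simulate_roster <- function(config) {
  validate_sim_config(config)
  with_seed(child_seed(config$rng_seed, 1L), {
    areas <- rep(names(config$n_individuals_per_area),
                 times = config$n_individuals_per_area)
    n <- length(areas)
    sex <- sample(c("male", "female", "subadult"), n, replace = TRUE,
                  prob = config$sex_proportions)
    mcl_mean <- c(male = 26, female = 22, subadult = 12)[sex]
    mcl_sd <- c(male = 2, female = 1.5, subadult = 2.5)[sex]
    transloc <- ifelse(
      areas == names(config$n_individuals_per_area)[1],
      stats::rbinom(n, 1L, config$p_translocated_release), 0L)
    data.frame(
      tortoise_id = sprintf("T%03d", seq_len(n)),
      sex = sex,
      area = areas,
      translocated = as.integer(transloc),
      mcl_cm = round(pmax(4, stats::rnorm(n, mcl_mean, mcl_sd)), 1),
      stringsAsFactors = FALSE)
  })
}

#' Simulate area-level daily weather and greenness series
#'
#' Sinusoidal seasonal maximum temperature with AR(1) noise, Gamma-distributed
#' rain on stochastic wet days (winter- and monsoon-weighted), and a smooth
#' spring-peaked NDVI curve with small noise. The series starts on January 1
#' of the year before the first study year so preceding-winter windows are
#' always covered.
#'
#' @param config a [sim_config()].
#' @return data.frame `area`, `date`, `tmax_c`, `rain_mm`, `ndvi` with one
#'   row per area-day.
#' @export
simulate_weather <- function(config) {
  validate_sim_config(config)
  with_seed(child_seed(config$rng_seed, 2L), {
    dates <- seq(as.Date(sprintf("%d-01-01", min(config$years) - 1L)),
                 as.Date(sprintf("%d-12-31", max(config$years))), by = "day")
    doy <- as.integer(format(dates, "%j"))
    nd <- length(dates)
    out <- vector("list", length(config$n_individuals_per_area))
    for (a in seq_along(out)) {
      seasonal <- 27 + 13 * cos(2 * pi * (doy - 196) / 365.25)
      e <- stats::filter(stats::rnorm(nd, 0, 2), 0.7, method = "recursive")
      tmax <- seasonal + as.numeric(e) + stats::rnorm(1, 0, 0.5)
      p_wet <- ifelse(doy < 90 | doy > 330, 0.10,
                      ifelse(doy > 182 & doy < 274, 0.08, 0.03))
      rain <- stats::rbinom(nd, 1L, p_wet) *
        stats::rgamma(nd, shape = 0.8, scale = 6)
      ndvi <- 0.095 + 0.035 * exp(-((doy - 100) / 45)^2) +
        as.numeric(stats::filter(stats::rnorm(nd, 0, 0.004), 0.9,
                                 method = "recursive"))
      out[[a]] <- data.frame(
        area = names(config$n_individuals_per_area)[a],
        date = dates,
        tmax_c = round(tmax, 2),
        rain_mm = round(rain, 2),
        ndvi = round(pmax(0.05, ndvi), 4),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

# Split a weather table into per-area cumulative-sum indexes for O(1)
# window aggregation. Dates must be consecutive within each area.
.wx_index <- function(weather) {
  lapply(split(weather, weather$area), function(w) {
    w <- w[order(w$date), ]
    d <- as.numeric(w$date)
    if (any(diff(d) != 1))
      stop_acm("weather series has gaps for area ", w$area[1])
    list(d0 = d[1], n = nrow(w),
         ctmax = cumsum(w$tmax_c), crain = cumsum(w$rain_mm),
         cndvi = cumsum(w$ndvi))
  })
}

# Sum of `col` over dates [end_date - ndays, end_date - 1]; the window ends
# the day before `end_date`.
.wx_window_sum <- function(idx, end_date, ndays, col) {
  e <- as.numeric(end_date)
  i2 <- e - 1 - idx$d0 + 1          # index of last day in window
  i1 <- e - ndays - idx$d0 + 1      # index of first day in window
  if (i1 < 1 || i2 > idx$n)
    stop_acm("window [", ndays, " d before ", as.Date(e, origin = "1970-01-01"),
             "] extends outside the weather series")
  cs <- idx[[col]]
  cs[i2] - (if (i1 > 1) cs[i1 - 1] else 0)
}

# Vectorized variant of .wx_window_sum over many end dates (numeric).
.wx_window_sum_vec <- function(idx, end_num, ndays, col) {
  i2 <- end_num - 1 - idx$d0 + 1
  i1 <- end_num - ndays - idx$d0 + 1
  if (any(i1 < 1) || any(i2 > idx$n))
    stop_acm("a ", ndays, "-day window extends outside the weather series")
  cs <- idx[[col]]
  cs[i2] - ifelse(i1 > 1, cs[i1 - 1], 0)
}

# Landscape/site context of an activity center, redrawn on relocation.
.draw_site <- function(config, area) {
  list(fence = stats::rbinom(1L, 1L, config$p_fence[[area]]),
       minor_road = stats::rbinom(1L, 1L, config$p_minor_road),
       major_road = stats::rbinom(1L, 1L, config$p_major_road),
       slope = round(stats::rgamma(1L, shape = 1.7, scale = 1.3), 2),
       roughness = round(1 + stats::rgamma(1L, shape = 0.45, scale = 0.45), 2),
       wash = round(100 * stats::rbeta(1L, 5.6, 48.2), 1),
       shrub = round(pmin(27, pmax(0.1, stats::rnorm(1L, 13.7, 5.1))), 1))
}

.beta_get <- function(beta, nm) if (nm %in% names(beta)) beta[[nm]] else 0

#' Simulate encounter histories with known movement states
#'
#' Generates, per individual and active season, a weekly encounter sequence.
#' Each step's latent state (within = 0 / among = 1 activity centers) is drawn
#' from a logistic model combining `beta_truth`, nested random intercepts
#' (individual within area), and the log encounter-interval offset; the step
#' length is then drawn from the corresponding per-sex log-normal. Among-
#' center steps relocate the activity-center anchor and redraw its landscape
#' context; headings are uniform on the circle.
#'
#' @param config a [sim_config()].
#' @param roster output of [simulate_roster()].
#' @param weather optional output of [simulate_weather()]; generated from
#'   `config` when omitted.
#' @return list with elements `encounters` (one row per telemetry fix),
#'   `weather`, `burrows` (all activity-center sites ever occupied) and
#'   `truth` (class `acm_truth`: per-step latent states and realized random
#'   intercepts, with the `beta_truth` echo).
#' @export
simulate_encounters <- function(config, roster, weather = NULL) {
  validate_sim_config(config)
  if (is.null(weather)) weather <- simulate_weather(config)
  wx <- .wx_index(weather)
  areas <- names(config$n_individuals_per_area)
  centers <- data.frame(area = areas,
                        cx = 20000 * (seq_along(areas) - 1), cy = 0)
  b <- config$beta_truth

  with_seed(child_seed(config$rng_seed, 3L), {
    b_area <- stats::setNames(stats::rnorm(length(areas), 0, config$re_sd_area),
                              areas)
    b_ind <- stats::setNames(
      stats::rnorm(nrow(roster), 0, config$re_sd_individual),
      roster$tortoise_id)

    enc_list <- list(); step_list <- list(); burrow_list <- list()
    burrow_n <- 0L

    for (r in seq_len(nrow(roster))) {
      id <- roster$tortoise_id[r]
      sex <- roster$sex[r]
      area <- roster$area[r]
      ctr <- centers[centers$area == area, ]
      pos <- c(ctr$cx + stats::runif(1, -1500, 1500),
               ctr$cy + stats::runif(1, -1500, 1500))
      site <- .draw_site(config, area)
      burrow_n <- burrow_n + 1L
      burrow_list[[burrow_n]] <- data.frame(
        burrow_id = sprintf("B%05d", burrow_n), area = area,
        x_m = pos[1], y_m = pos[2], stringsAsFactors = FALSE)
      wpar <- config$within_distance_params[[sex]]
      apar <- config$among_distance_params[[sex]]

      for (yr in config$years) {
        year0 <- as.Date(sprintf("%d-01-01", yr)) - 1L
        t <- config$season_days[1] + sample.int(7L, 1L) - 1L
        dts <- integer(0)
        while (t <= config$season_days[2]) {
          dts <- c(dts, t)
          gap <- stats::runif(1) < config$gap_probability
          rng <- if (gap) config$gap_interval_days else config$encounter_interval_days
          iv_choices <- seq(rng[1], rng[2])
          t <- t + if (length(iv_choices) == 1L) iv_choices
                   else sample(iv_choices, 1L)
        }
        ne <- length(dts)
        if (ne == 0L) next
        dates <- year0 + dts

        # state-independent part of the step linear predictors
        eta_base <- numeric(max(ne - 1L, 0L))
        tmax32 <- rain32 <- numeric(max(ne - 1L, 0L))
        if (ne > 1L) for (i in 2:ne) {
          mid <- midpoint_date(dates[i - 1L], dates[i])
          ds <- scale_day(as.integer(format(mid, "%j")))
          tm <- .wx_window_sum(wx[[area]], mid, 32L, "ctmax") / 32
          rn <- .wx_window_sum(wx[[area]], mid, 32L, "crain")
          cat32 <- as.character(categorize_rain(rn, window = "32"))
          eta_base[i - 1L] <- b[["(Intercept)"]] +
            .beta_get(b, paste0("year", yr)) +
            .beta_get(b, "day") * ds +
            .beta_get(b, "day2") * ds^2 +
            .beta_get(b, "day3") * ds^3 +
            .beta_get(b, paste0("year", yr, ":day")) * ds +
            .beta_get(b, paste0("year", yr, ":day2")) * ds^2 +
            .beta_get(b, paste0("year", yr, ":day3")) * ds^3 +
            .beta_get(b, paste0("sex", sex)) +
            .beta_get(b, paste0("day:sex", sex)) * ds +
            .beta_get(b, "tmax_32") * (tm - .tmax_center) +
            .beta_get(b, paste0("rain_32_cat", cat32)) +
            .beta_get(b, paste0("tmax_32:rain_32_cat", cat32)) *
              (tm - .tmax_center)
          tmax32[i - 1L] <- tm; rain32[i - 1L] <- rn
        }

        xs <- ys <- numeric(ne)
        fence <- minor <- major <- integer(ne)
        slope <- rough <- wash <- shrub <- numeric(ne)
        states <- dists <- etas <- rep(NA_real_, ne)
        for (i in seq_len(ne)) {
          if (i > 1L) {
            interval <- dts[i] - dts[i - 1L]
            eta <- eta_base[i - 1L] +
              site$fence * .beta_get(b, "fencing") +
              site$minor_road * .beta_get(b, "minor_roads") +
              b_ind[[id]] + b_area[[area]] + log(interval)
            st <- stats::rbinom(1L, 1L, stats::plogis(eta))
            par <- if (st == 1L) apar else wpar
            d <- stats::rlnorm(1L, par[["meanlog"]], par[["sdlog"]])
            th <- stats::runif(1L, 0, 2 * pi)
            pos <- pos + d * c(cos(th), sin(th))
            states[i] <- st; dists[i] <- d; etas[i] <- eta
            if (st == 1L) {
              site <- .draw_site(config, area)
              burrow_n <- burrow_n + 1L
              burrow_list[[burrow_n]] <- data.frame(
                burrow_id = sprintf("B%05d", burrow_n), area = area,
                x_m = pos[1], y_m = pos[2], stringsAsFactors = FALSE)
            }
          }
          xs[i] <- pos[1]; ys[i] <- pos[2]
          fence[i] <- site$fence; minor[i] <- site$minor_road
          major[i] <- site$major_road
          slope[i] <- site$slope; rough[i] <- site$roughness
          wash[i] <- site$wash; shrub[i] <- site$shrub
        }

        enc_list[[length(enc_list) + 1L]] <- data.frame(
          tortoise_id = id, date = dates,
          x_m = round(xs, 2), y_m = round(ys, 2),
          in_burrow = stats::rbinom(ne, 1L, 1 - config$p_out_of_burrow),
          area = area,
          fence_present = fence, minor_road_present = minor,
          major_road_present = major,
          slope_deg = slope, roughness_deg = rough,
          wash_pct = wash, shrub_pct = shrub,
          stringsAsFactors = FALSE)
        if (ne > 1L)
          step_list[[length(step_list) + 1L]] <- data.frame(
            tortoise_id = id,
            t_start = dates[-ne], t_end = dates[-1L],
            interval_days = diff(dts),
            latent_state = as.integer(states[-1L]),
            distance_m = dists[-1L],
            eta = etas[-1L],
            tmax_32 = tmax32, rain_32 = rain32,
            stringsAsFactors = FALSE)
      }
    }

    steps <- if (length(step_list)) do.call(rbind, step_list) else
      data.frame(tortoise_id = character(0), t_start = as.Date(character(0)),
                 t_end = as.Date(character(0)), interval_days = integer(0),
                 latent_state = integer(0), distance_m = numeric(0),
                 eta = numeric(0), tmax_32 = numeric(0), rain_32 = numeric(0))
    rownames(steps) <- NULL
    truth <- structure(list(
      steps = steps,
      re_individual = data.frame(tortoise_id = names(b_ind),
                                 intercept = as.numeric(b_ind),
                                 stringsAsFactors = FALSE),
      re_area = data.frame(area = names(b_area),
                           intercept = as.numeric(b_area),
                           stringsAsFactors = FALSE),
      beta_truth = b), class = "acm_truth")
    encounters <- do.call(rbind, enc_list)
    rownames(encounters) <- NULL
    burrows <- do.call(rbind, burrow_list)
    rownames(burrows) <- NULL
    list(encounters = encounters, weather = weather,
         burrows = burrows, truth = truth)
  })
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: roster, weather, encounters, burrows and truth in one
#' call.
#'
#' @param config a [sim_config()].
#' @return list with `roster`, `encounters`, `weather`, `burrows`, `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  roster <- simulate_roster(config)
  sim <- simulate_encounters(config, roster)
  c(list(roster = roster), sim)
}

#' @export
print.acm_truth <- function(x, ...) {
  cat(sprintf("Truth record: %d steps, %d individuals, %d areas; among fraction %.3f\n",
              nrow(x$steps), nrow(x$re_individual), nrow(x$re_area),
              if (nrow(x$steps)) mean(x$steps$latent_state) else NA_real_))
  invisible(x)
}

#' Write a truth record to JSON
#'
#' @param truth an `acm_truth` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_truth <- function(truth, path) {
  stopifnot(inherits(truth, "acm_truth"))
  obj <- list(
    steps = within(truth$steps, {
      t_start <- as.character(t_start); t_end <- as.character(t_end)
    }),
    re_individual = truth$re_individual,
    re_area = truth$re_area,
    beta_truth = as.list(truth$beta_truth))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a truth record written by [export_truth()]
#'
#' @param path JSON file path.
#' @return an `acm_truth` object.
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  steps <- as.data.frame(obj$steps, stringsAsFactors = FALSE)
  if (nrow(steps)) {
    steps$t_start <- as.Date(steps$t_start)
    steps$t_end <- as.Date(steps$t_end)
  }
  structure(list(
    steps = steps,
    re_individual = as.data.frame(obj$re_individual, stringsAsFactors = FALSE),
    re_area = as.data.frame(obj$re_area, stringsAsFactors = FALSE),
    beta_truth = unlist(obj$beta_truth)), class = "acm_truth")
}
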