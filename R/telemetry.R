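# Encounter retention rules and movement-record construction.
#
# Retention mirrors standard quality rules for weekly burrow telemetry:
# active-season months only, study years only, burrow-confirmed fixes (in a
# burrow at t and at t-1 or t+1), and 5-8 day spacing relative to a
# neighbouring encounter. Movements are straight-line (Euclidean)
# displacements between consecutive retained encounters.

#' Encounter retention rules
#'
#' @param months calendar months retained (default May-October).
#' @param interval_min,interval_max inclusive bounds (days) on the encounter
#'   interval used both for retention and for pairing movements.
#' @param years calendar years retained; `NULL` keeps all.
#' @param burrow_rule if `TRUE`, keep an encounter only when the animal was
#'   in a burrow at time t and also at t - 1 or t + 1.
#' @return an object of class `filter_rules`.
#' @export
filter_rules <- function(months = 5:10, interval_min = 5L, interval_max = 8L,
                         years = NULL, burrow_rule = TRUE) {
  interval_min <- as.integer(interval_min); interval_max <- as.integer(interval_max)
  if (interval_min < 1L || interval_min > interval_max)
    stop_acm("filter rules require 1 <= interval_min <= interval_max")
  structure(list(months = as.integer(months), interval_min = interval_min,
                 interval_max = interval_max,
                 years = if (is.null(years)) NULL else as.integer(years),
                 burrow_rule = isTRUE(burrow_rule)),
            class = "filter_rules")
}

#' @export
print.filter_rules <- function(x, ...) {
  cat(sprintf("Retention rules: months {%s}, interval %d-%d d, years %s, burrow rule %s\n",
              paste(x$months, collapse = ","), x$interval_min, x$interval_max,
              if (is.null(x$years)) "all" else paste(x$years, collapse = ","),
              if (x$burrow_rule) "on" else "off"), ...)
  invisible(x)
}

.check_encounters <- function(encounters) {
  need <- c("tortoise_id", "date", "x_m", "y_m", "in_burrow")
  miss <- setdiff(need, names(encounters))
  if (length(miss))
    stop_acm("encounters lack columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(encounters$x_m)) || !all(is.finite(encounters$y_m)))
    stop_acm("validation error: non-finite coordinates")
  o <- order(encounters$tortoise_id, encounters$date)
  enc <- encounters[o, , drop = FALSE]
  same <- enc$tortoise_id[-1] == enc$tortoise_id[-nrow(enc)]
  dd <- diff(as.numeric(enc$date))
  if (nrow(enc) > 1 && any(same & dd <= 0)) {
    bad <- enc$tortoise_id[-1][same & dd <= 0][1]
    stop_acm("validation error: duplicate or non-increasing encounter dates ",
             "for individual ", bad)
  }
  enc
}

#' Apply encounter retention rules
#'
#' Rules are applied to each individual's date-ordered sequence and iterated
#' to a fixed point (dropping an encounter changes its neighbours' context),
#' so re-applying the filter to its own output is a no-op.
#'
#' @param encounters data.frame of telemetry fixes (`tortoise_id`, `date`,
#'   `x_m`, `y_m`, `in_burrow`, ...). Dates must be strictly increasing
#'   within an individual.
#' @param rules a [filter_rules()] object.
#' @return the retained subset of `encounters` (same columns).
#' @export
filter_encounters <- function(encounters, rules = filter_rules()) {
  stopifnot(inherits(rules, "filter_rules"))
  enc <- .check_encounters(encounters)
  mo <- as.integer(format(enc$date, "%m"))
  keep <- mo %in% rules$months
  if (!is.null(rules$years))
    keep <- keep & as.integer(format(enc$date, "%Y")) %in% rules$years
  enc <- enc[keep, , drop = FALSE]

  repeat {
    n0 <- nrow(enc)
    if (n0 == 0L) break
    id <- enc$tortoise_id
    d <- as.numeric(enc$date)
    prev_same <- c(FALSE, id[-1] == id[-n0])
    next_same <- c(id[-1] == id[-n0], FALSE)
    gap_prev <- c(NA, diff(d)); gap_prev[!prev_same] <- NA
    gap_next <- c(gap_prev[-1], NA); gap_next[!next_same] <- NA
    keep <- rep(TRUE, n0)
    if (rules$burrow_rule) {
      inb <- enc$in_burrow == 1
      nb_prev <- c(FALSE, inb[-n0]) & prev_same
      nb_next <- c(inb[-1], FALSE) & next_same
      keep <- inb & (nb_prev | nb_next)
    }
    ok_prev <- !is.na(gap_prev) & gap_prev >= rules$interval_min &
      gap_prev <= rules$interval_max
    ok_next <- !is.na(gap_next) & gap_next >= rules$interval_min &
      gap_next <= rules$interval_max
    keep <- keep & (ok_prev | ok_next)
    enc <- enc[keep, , drop = FALSE]
    if (nrow(enc) == n0) break
  }
  rownames(enc) <- NULL
  enc
}

#' Build movement records from retained encounters
#'
#' One record per consecutive retained encounter pair separated by
#' `interval_min`-`interval_max` days: Euclidean displacement, coordinate
#' midpoint, Julian day of the calendar midpoint, log-interval offset, and
#' the sex class joined from the roster. Site covariates carried on the
#' encounters table (fence/road presence, slope, roughness, wash, shrub) ride
#' along from the starting encounter of each pair.
#'
#' @param encounters retained encounters (see [filter_encounters()]).
#' @param roster data.frame with `tortoise_id` and `sex` (and optionally
#'   `translocated`, `mcl_cm`).
#' @param interval_min,interval_max inclusive pairing bounds in days.
#' @return data.frame of class `acm_movements`; `is_acm` is `NA` until
#'   [classify_movements()] fills it.
#' @export
build_movements <- function(encounters, roster, interval_min = 5L,
                            interval_max = 8L) {
  enc <- .check_encounters(encounters)
  missing_ids <- setdiff(unique(enc$tortoise_id), roster$tortoise_id)
  if (length(missing_ids))
    stop_acm("individuals missing from roster: ",
             paste(missing_ids, collapse = ", "))
  n <- nrow(enc)
  if (n < 2L) return(.empty_movements())
  same <- enc$tortoise_id[-1] == enc$tortoise_id[-n]
  gap <- diff(as.numeric(enc$date))
  take <- same & gap >= interval_min & gap <= interval_max
  i0 <- which(take); i1 <- i0 + 1L
  if (!length(i0)) return(.empty_movements())
  mid <- midpoint_date(enc$date[i0], enc$date[i1])
  mv <- data.frame(
    tortoise_id = enc$tortoise_id[i0],
    t_start = enc$date[i0], t_end = enc$date[i1],
    interval_days = as.integer(gap[i0]),
    distance_m = sqrt((enc$x_m[i1] - enc$x_m[i0])^2 +
                        (enc$y_m[i1] - enc$y_m[i0])^2),
    midpoint_x_m = (enc$x_m[i0] + enc$x_m[i1]) / 2,
    midpoint_y_m = (enc$y_m[i0] + enc$y_m[i1]) / 2,
    julian_day_mid = as.integer(format(mid, "%j")),
    year = as.integer(format(mid, "%Y")),
    offset_log_interval = log(as.numeric(gap[i0])),
    stringsAsFactors = FALSE)
  ros <- roster[match(mv$tortoise_id, roster$tortoise_id), , drop = FALSE]
  mv$sex <- ros$sex
  if ("area" %in% names(enc)) mv$area <- enc$area[i0]
  if ("translocated" %in% names(ros)) mv$translocated <- ros$translocated
  if ("mcl_cm" %in% names(ros)) mv$mcl_cm <- ros$mcl_cm
  for (col in c("fence_present", "minor_road_present", "major_road_present",
                "slope_deg", "roughness_deg", "wash_pct", "shrub_pct"))
    if (col %in% names(enc)) mv[[col]] <- enc[[col]][i0]
  mv$is_acm <- NA_integer_
  rownames(mv) <- NULL
  class(mv) <- c("acm_movements", "data.frame")
  mv
}

.empty_movements <- function() {
  mv <- data.frame(tortoise_id = character(0),
                   t_start = as.Date(character(0)),
                   t_end = as.Date(character(0)),
                   interval_days = integer(0), distance_m = numeric(0),
                   midpoint_x_m = numeric(0), midpoint_y_m = numeric(0),
                   julian_day_mid = integer(0), year = integer(0),
                   offset_log_interval = numeric(0), sex = character(0),
                   is_acm = integer(0), stringsAsFactors = FALSE)
  class(mv) <- c("acm_movements", "data.frame")
  mv
}

#' Summarize movement distances
#'
#' Order statistics use the default linear-interpolation quantile convention
#' (type 7).
#'
#' @param movements an `acm_movements` data.frame.
#' @return list with `n`, `n_individuals`, `median_m`, `iqr_m` (25th/75th
#'   percentiles), and `mean_moves_per_individual_year`; an empty-summary
#'   sentinel (`n = 0`, `NA` statistics) for empty input.
#' @export
summarize_distances <- function(movements) {
  if (is.null(movements) || nrow(movements) == 0L)
    return(list(n = 0L, n_individuals = 0L, median_m = NA_real_,
                iqr_m = c(NA_real_, NA_real_),
                mean_moves_per_individual_year = NA_real_))
  q <- stats::quantile(movements$distance_m, c(0.25, 0.5, 0.75),
                       names = FALSE, type = 7)
  per_iy <- table(movements$tortoise_id, movements$year)
  list(n = nrow(movements),
       n_individuals = length(unique(movements$tortoise_id)),
       median_m = q[2], iqr_m = c(q[1], q[3]),
       mean_moves_per_individual_year = mean(per_iy[per_iy > 0]))
}
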