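# Covariate assembly per movement record: use areas, density indices,
# temporal-window aggregation, rainfall categorization, residualization, and
# polynomial/interaction date terms.

#' Use-area radii by sex class
#'
#' Circular local use areas within which spatial covariates are sampled,
#' centred on the geographic midpoint between burrow encounters.
#'
#' @param radius_m named radii in metres (defaults: male 180, female 120,
#'   subadult 60 — approximately 10.2, 4.5, and 1.1 ha).
#' @return object of class `use_area_spec` with `radius_m` and derived
#'   `area_ha`.
#' @export
use_area_spec <- function(radius_m = c(male = 180, female = 120, subadult = 60)) {
  if (any(radius_m <= 0)) stop_acm("use-area radii must be > 0")
  structure(list(radius_m = radius_m,
                 area_ha = pi * radius_m^2 / 1e4),
            class = "use_area_spec")
}

#' Circular use area of one movement
#'
#' @param movement a single-row `acm_movements` data.frame (or any list with
#'   `midpoint_x_m`, `midpoint_y_m`, `sex`).
#' @param spec a [use_area_spec()].
#' @return list `center` (x, y), `radius_m`, `area_ha`.
#' @export
use_area <- function(movement, spec = use_area_spec()) {
  sex <- as.character(movement$sex[1])
  if (!sex %in% names(spec$radius_m))
    stop_acm("unknown sex class: ", sex)
  list(center = c(x = movement$midpoint_x_m[1], y = movement$midpoint_y_m[1]),
       radius_m = unname(spec$radius_m[sex]),
       area_ha = unname(spec$area_ha[sex]))
}

#' Local tortoise density index
#'
#' Number of distinct other radio-marked individuals with at least one
#' encounter inside the movement's use area dated within a week before the
#' start or after the end of the movement, divided by the use-area hectares.
#'
#' @param encounters full encounter table.
#' @param movement single movement record.
#' @param spec a [use_area_spec()].
#' @param window_days time slack around the movement (default 7).
#' @return animals per hectare.
#' @export
density_index <- function(encounters, movement, spec = use_area_spec(),
                          window_days = 7L) {
  ua <- use_area(movement, spec)
  d <- as.numeric(encounters$date)
  sel <- d >= as.numeric(movement$t_start) - window_days &
    d <= as.numeric(movement$t_end) + window_days &
    encounters$tortoise_id != movement$tortoise_id
  if (!any(sel)) return(0)
  e <- encounters[sel, ]
  inside <- (e$x_m - ua$center[["x"]])^2 + (e$y_m - ua$center[["y"]])^2 <=
    ua$radius_m^2
  length(unique(e$tortoise_id[inside])) / ua$area_ha
}

#' Local burrow density index
#'
#' Distinct burrow sites ever used that fall inside the movement's use area,
#' divided by the use-area hectares (no time window).
#'
#' @param burrows data.frame with `burrow_id`, `x_m`, `y_m`.
#' @param movement single movement record.
#' @param spec a [use_area_spec()].
#' @return burrows per hectare.
#' @export
burrow_density_index <- function(burrows, movement, spec = use_area_spec()) {
  ua <- use_area(movement, spec)
  inside <- (burrows$x_m - ua$center[["x"]])^2 +
    (burrows$y_m - ua$center[["y"]])^2 <= ua$radius_m^2
  length(unique(burrows$burrow_id[inside])) / ua$area_ha
}

#' Aggregate a daily series over a movement-anchored window
#'
#' Fixed-length windows span exactly `window` days and end the day before
#' `end_date`; the `active` window is Apr 1 - Oct 31 of `end_date`'s year and
#' `winter` is Nov 1 of the prior year through Mar 31.
#'
#' @param series data.frame with `date` and a value column.
#' @param end_date anchor date (the movement midpoint).
#' @param window one of `"16"`, `"32"`, `"active"`, `"winter"`, or an
#'   integer day count.
#' @param stat `"mean"` or `"sum"`.
#' @param value column name of the daily value.
#' @return scalar aggregate; errors listing missing days when the series
#'   does not cover the window.
#' @export
window_aggregate <- function(series, end_date, window, stat = c("mean", "sum"),
                             value = "value") {
  stat <- match.arg(stat)
  end_date <- as.Date(end_date)
  yr <- as.integer(format(end_date, "%Y"))
  if (is.numeric(window)) window <- as.character(as.integer(window))
  span <- switch(window,
    "16" = c(end_date - 16L, end_date - 1L),
    "32" = c(end_date - 32L, end_date - 1L),
    active = as.Date(sprintf(c("%d-04-01", "%d-10-31"), yr)),
    winter = c(as.Date(sprintf("%d-11-01", yr - 1L)),
               as.Date(sprintf("%d-03-31", yr))),
    stop_acm("unknown window: ", window))
  wanted <- seq(span[1], span[2], by = "day")
  idx <- match(wanted, series$date)
  if (anyNA(idx)) {
    gaps <- wanted[is.na(idx)]
    stop_acm("daily series is missing ", length(gaps), " day(s) in window (",
             paste(utils::head(gaps, 5), collapse = ", "),
             if (length(gaps) > 5) ", ..." else "", ")")
  }
  v <- series[[value]][idx]
  if (stat == "mean") mean(v) else sum(v)
}

#' Categorize a rainfall total
#'
#' Half-open bins: for the 32-day window low < 1 mm, medium in [1, 7.6) mm,
#' high >= 7.6 mm; for the 16-day window the medium/high cut is 4.5 mm.
#'
#' @param total_mm nonnegative rainfall total(s), mm.
#' @param window `"32"` or `"16"`.
#' @return factor with levels `low`, `medium`, `high`.
#' @export
categorize_rain <- function(total_mm, window = c("32", "16")) {
  window <- match.arg(as.character(window), c("32", "16"))
  if (any(total_mm < 0, na.rm = TRUE)) stop_acm("negative rainfall total")
  hi <- if (window == "32") 7.6 else 4.5
  out <- ifelse(total_mm < 1, "low", ifelse(total_mm < hi, "medium", "high"))
  factor(out, levels = c("low", "medium", "high"))
}

#' Residualize a covariate on a categorical confounder
#'
#' Ordinary-least-squares residuals of `values` on the factor `conditioning`
#' (i.e., deviations from level means); residuals sum to zero within each
#' level.
#'
#' @param values numeric vector.
#' @param conditioning categorical labels, same length.
#' @param drop_unused drop empty factor levels instead of erroring on them.
#' @return numeric residuals.
#' @export
residualize <- function(values, conditioning, drop_unused = FALSE) {
  conditioning <- as.factor(conditioning)
  if (drop_unused) conditioning <- droplevels(conditioning)
  if (nlevels(conditioning) < 2L)
    stop_acm("residualization needs at least 2 conditioning levels")
  if (any(table(conditioning) == 0L))
    stop_acm("conditioning level with zero observations: ",
             paste(levels(conditioning)[table(conditioning) == 0],
                   collapse = ", "))
  values - stats::ave(values, conditioning, FUN = mean)
}

#' Polynomial date terms for one or more movements
#'
#' The Julian day is centred and scaled ([scale_day()]) before powers are
#' formed.
#'
#' @param julian_day integer day(s) of year of the movement midpoint.
#' @param year calendar year(s).
#' @return data.frame `year` (factor), `day`, `day2`, `day3`.
#' @export
temporal_terms <- function(julian_day, year) {
  ds <- scale_day(julian_day)
  data.frame(year = factor(year), day = ds, day2 = ds^2, day3 = ds^3)
}

# Table of the covariate columns the model stage expects.
.covariate_columns <- c(
  "year", "day", "day2", "day3", "area", "sex", "translocated", "mcl_resid",
  "density_resid", "slope", "roughness_resid", "wash_pct", "minor_roads",
  "major_roads", "fencing", "burrows_resid", "ndvi_start_resid",
  "ndvi_active", "ndvi_32", "ndvi_16", "shrub_pct", "tmax_active", "tmax_32",
  "tmax_16", "rain_winter_resid", "rain_active", "rain_32_cat", "rain_16_cat",
  "offset_log_interval", "is_acm")

#' Assemble the per-movement covariate table
#'
#' One row per movement record with temporal, individual, landscape,
#' vegetation, and weather covariates: window aggregates end the day before
#' the movement midpoint; 32/16-day rainfall totals are categorized; MCL,
#' tortoise density, roughness and burrow density are residualized on sex
#' class, starting NDVI and winter precipitation on year. Slope, roughness,
#' wash, shrub and the road/fence presences come from the per-record values
#' carried on the movements (simulator-supplied site context).
#'
#' @param movements classified `acm_movements`.
#' @param encounters full encounter table (for the tortoise density index).
#' @param weather daily weather table (`area`, `date`, `tmax_c`, `rain_mm`,
#'   `ndvi`).
#' @param burrows optional burrow table (`burrow_id`, `x_m`, `y_m`).
#' @param spec a [use_area_spec()].
#' @param compute_density_indices set `FALSE` to skip the two O(n^2) density
#'   indices (their columns are then 0 before residualization).
#' @return data.frame of class `acm_covariates` with the full covariate
#'   column set; the build fails listing any missing ingredient.
#' @export
build_covariate_table <- function(movements, encounters, weather,
                                  burrows = NULL, spec = use_area_spec(),
                                  compute_density_indices = TRUE) {
  if (nrow(movements) == 0L) stop_acm("no movements to build covariates for")
  need <- c("fence_present", "minor_road_present", "major_road_present",
            "slope_deg", "roughness_deg", "wash_pct", "shrub_pct",
            "translocated", "mcl_cm", "area")
  miss <- setdiff(need, names(movements))
  if (length(miss))
    stop_acm("movements lack per-record covariates: ",
             paste(miss, collapse = ", "))
  wx <- .wx_index(weather)
  mv <- movements
  mid <- as.Date(mv$t_start) + floor((as.numeric(mv$t_end) -
                                        as.numeric(mv$t_start)) / 2)

  n <- nrow(mv)
  mid_num <- as.numeric(mid)
  yr_mid <- as.integer(format(mid, "%Y"))
  area_rows <- split(seq_len(n), mv$area)
  # movement-anchored fixed windows, vectorized by area
  agg <- function(col, ndays, denom = 1) {
    out <- numeric(n)
    for (a in names(area_rows)) {
      ii <- area_rows[[a]]
      out[ii] <- .wx_window_sum_vec(wx[[a]], mid_num[ii], ndays, col) / denom
    }
    out
  }
  # calendar windows, constant within area-year
  by_span <- function(col, stat, span_fun) {
    out <- numeric(n)
    for (a in names(area_rows)) for (y in unique(yr_mid[area_rows[[a]]])) {
      ii <- area_rows[[a]][yr_mid[area_rows[[a]]] == y]
      sp <- span_fun(y)
      nd <- as.numeric(sp[2]) - as.numeric(sp[1]) + 1
      tot <- .wx_window_sum(wx[[a]], sp[2] + 1L, nd, col)
      out[ii] <- if (stat == "mean") tot / nd else tot
    }
    out
  }
  season <- function(col, stat) by_span(col, stat, function(y)
    as.Date(sprintf(c("%d-04-01", "%d-10-31"), y)))
  winter <- function(col, stat) by_span(col, stat, function(y)
    c(as.Date(sprintf("%d-11-01", y - 1L)), as.Date(sprintf("%d-03-31", y))))
  ndvi_start <- by_span("cndvi", "mean", function(y)
    as.Date(sprintf(c("%d-03-20", "%d-03-31"), y)))

  dens <- burr <- numeric(n)
  if (compute_density_indices) {
    for (i in seq_len(n)) {
      dens[i] <- density_index(encounters, mv[i, , drop = FALSE], spec)
      if (!is.null(burrows))
        burr[i] <- burrow_density_index(burrows, mv[i, , drop = FALSE], spec)
    }
  }

  tt <- temporal_terms(mv$julian_day_mid, mv$year)
  # absent classes would create all-zero design columns downstream
  sexf <- droplevels(factor(mv$sex, levels = c("male", "female", "subadult")))
  rain32 <- agg("crain", 32L)
  rain16 <- agg("crain", 16L)
  out <- data.frame(
    tortoise_id = mv$tortoise_id,
    t_start = mv$t_start,
    year = tt$year, day = tt$day, day2 = tt$day2, day3 = tt$day3,
    area = factor(mv$area),
    sex = sexf,
    translocated = mv$translocated,
    mcl_resid = residualize(mv$mcl_cm, sexf, drop_unused = TRUE),
    density_resid = residualize(dens, sexf, drop_unused = TRUE),
    slope = mv$slope_deg,
    roughness_resid = residualize(mv$roughness_deg, sexf, drop_unused = TRUE),
    wash_pct = mv$wash_pct,
    minor_roads = mv$minor_road_present,
    major_roads = mv$major_road_present,
    fencing = mv$fence_present,
    burrows_resid = residualize(burr, sexf, drop_unused = TRUE),
    ndvi_start_resid = residualize(ndvi_start, tt$year, drop_unused = TRUE),
    ndvi_active = season("cndvi", "mean"),
    ndvi_32 = agg("cndvi", 32L, denom = 32),
    ndvi_16 = agg("cndvi", 16L, denom = 16),
    shrub_pct = mv$shrub_pct,
    tmax_active = season("ctmax", "mean"),
    tmax_32 = agg("ctmax", 32L, denom = 32),
    tmax_16 = agg("ctmax", 16L, denom = 16),
    rain_winter_resid = residualize(winter("crain", "sum"), tt$year, drop_unused = TRUE),
    rain_active = season("crain", "sum"),
    rain_32_cat = categorize_rain(rain32, "32"),
    rain_16_cat = categorize_rain(rain16, "16"),
    offset_log_interval = mv$offset_log_interval,
    is_acm = mv$is_acm,
    stringsAsFactors = FALSE)
  missing_cols <- setdiff(.covariate_columns, names(out))
  if (length(missing_cols))
    stop_acm("covariate table is missing columns: ",
             paste(missing_cols, collapse = ", "))
  class(out) <- c("acm_covariates", "data.frame")
  out
}
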