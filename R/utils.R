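# Internal helpers shared across modules.

# Centering/scale constants for derived model covariates. Day is centered and
# scaled before polynomial terms are formed (raw cubic Julian days are
# numerically hostile); maximum temperatures are centered so that
# temperature-by-rain interaction columns are not near-collinear with the
# temperature main effect.
.day_center <- 194
.day_scale <- 47
.tmax_center <- 33

#' Scale a Julian day for use in polynomial date terms
#'
#' Centers at day-of-year 194 (mid July, the long-run mean encounter date)
#' and scales by 47 days before powers are formed.
#'
#' @param julian_day integer day of year.
#' @param center,scale centering and scaling constants (days).
#' @return numeric scaled day.
#' @export
scale_day <- function(julian_day, center = .day_center, scale = .day_scale) {
  (julian_day - center) / scale
}

# Calendar midpoint between two dates (floor of the mean).
midpoint_date <- function(t_start, t_end) {
  as.Date(floor((as.numeric(t_start) + as.numeric(t_end)) / 2),
          origin = "1970-01-01")
}

# Evaluate code under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a per-stage child seed from a root seed, staying below 2^31.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + 7919 * k) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_acm <- function(...) stop(..., call. = FALSE)
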