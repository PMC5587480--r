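test_that("use areas reproduce the sex-specific geometry", {
  spec <- use_area_spec()
  expect_equal(unname(spec$area_ha["male"]), pi * 180^2 / 1e4, tolerance = 1e-12)
  expect_lt(abs(spec$area_ha[["male"]] - 10.2), 0.05)
  expect_lt(abs(spec$area_ha[["female"]] - 4.5), 0.05)
  expect_lt(abs(spec$area_ha[["subadult"]] - 1.1), 0.05)

  mv <- data.frame(midpoint_x_m = 12, midpoint_y_m = -7, sex = "subadult")
  ua <- use_area(mv, spec)
  expect_equal(ua$center, c(x = 12, y = -7))
  expect_equal(ua$radius_m, 60)
  expect_error(use_area(data.frame(midpoint_x_m = 0, midpoint_y_m = 0,
                                   sex = "juvenile"), spec), "unknown")
  expect_error(use_area_spec(c(male = 0, female = 120, subadult = 60)), "> 0")
})

test_that("density indices count distinct neighbours per hectare", {
  mv <- data.frame(tortoise_id = "A", t_start = as.Date("2014-06-01"),
                   t_end = as.Date("2014-06-08"),
                   midpoint_x_m = 0, midpoint_y_m = 0, sex = "male")
  mk_enc <- function(id, date, x, y)
    data.frame(tortoise_id = id, date = as.Date(date), x_m = x, y_m = y)
  # no other individuals
  expect_equal(density_index(mk_enc("A", "2014-06-01", 0, 0), mv), 0)
  # one neighbour inside the male use area: 1 / 10.18 ha
  enc <- rbind(mk_enc("A", "2014-06-01", 0, 0),
               mk_enc("B", "2014-06-03", 50, 0),
               mk_enc("B", "2014-06-04", 60, 0))   # same animal counted once
  expect_equal(density_index(enc, mv), 1 / (pi * 180^2 / 1e4),
               tolerance = 1e-12)
  # outside the radius or the +/- 7 day window: not counted
  far <- rbind(mk_enc("C", "2014-06-03", 500, 0),
               mk_enc("D", "2014-07-01", 10, 0))
  expect_equal(density_index(rbind(enc[1, ], far), mv), 0)

  # burrows: three inside a female area -> 3 / 4.52 ha
  mvf <- transform(mv, sex = "female")
  burrows <- data.frame(burrow_id = c("b1", "b2", "b3", "b4"),
                        x_m = c(0, 10, -40, 900), y_m = c(5, 0, 20, 0))
  expect_equal(burrow_density_index(burrows, mvf), 3 / (pi * 120^2 / 1e4),
               tolerance = 1e-12)
  expect_equal(burrow_density_index(burrows[4, ], mvf), 0)
})

test_that("window aggregation spans exact windows ending before the midpoint", {
  dates <- seq(as.Date("2013-10-01"), as.Date("2014-12-31"), by = "day")
  ser <- data.frame(date = dates, value = 2)
  mid <- as.Date("2014-07-10")
  expect_equal(window_aggregate(ser, mid, "16", "sum"), 32)
  ser30 <- data.frame(date = dates, value = 30)
  expect_equal(window_aggregate(ser30, mid, "32", "mean"), 30)
  # ramp over the exact 32-day window [mid-32, mid-1]
  ramp <- data.frame(date = seq(mid - 32, mid - 1, by = "day"), value = 1:32)
  expect_equal(window_aggregate(ramp, mid, "32", "sum"), 528)
  # active season and winter spans
  expect_equal(window_aggregate(ser, mid, "active", "sum"),
               2 * as.numeric(as.Date("2014-10-31") - as.Date("2014-04-01") + 1))
  expect_equal(window_aggregate(ser, mid, "winter", "sum"),
               2 * as.numeric(as.Date("2014-03-31") - as.Date("2013-11-01") + 1))
  # gaps are reported
  gappy <- ser[-c(100:102), ]
  expect_error(window_aggregate(gappy, as.Date("2014-01-20"), "32", "sum"),
               "missing 3 day")
})

test_that("rainfall categorization follows the half-open cutpoints", {
  expect_equal(as.character(categorize_rain(0.5, "32")), "low")
  expect_equal(as.character(categorize_rain(1.0, "32")), "medium")
  expect_equal(as.character(categorize_rain(7.6, "32")), "high")
  expect_equal(as.character(categorize_rain(7.5, "32")), "medium")
  expect_equal(as.character(categorize_rain(4.4, "16")), "medium")
  expect_equal(as.character(categorize_rain(4.5, "16")), "high")
  expect_equal(as.character(categorize_rain(0.99, "16")), "low")
  expect_error(categorize_rain(-1, "32"), "negative")
  # total and deterministic over a sweep
  sweep <- categorize_rain(seq(0, 100, by = 0.1), "32")
  expect_false(anyNA(sweep))
})

test_that("residualization centres within conditioning levels", {
  expect_equal(residualize(c(5, 5, 9, 9), c("a", "a", "b", "b")),
               c(0, 0, 0, 0))
  expect_equal(residualize(c(1, 3, 10), c("A", "A", "B")), c(-1, 1, 0))
  v <- withr::with_seed(2, rnorm(60))
  g <- rep(c("x", "y", "z"), each = 20)
  r <- residualize(v, g)
  expect_lt(max(abs(tapply(r, g, sum))), 1e-9)
  expect_error(residualize(1:5, rep("a", 5)), "2 conditioning levels")
  expect_error(residualize(1:4, factor(c("a", "a", "b", "b"),
                                       levels = c("a", "b", "c"))),
               "zero observations")
})

test_that("temporal terms centre and scale the Julian day", {
  tt <- temporal_terms(194, 2014)
  expect_equal(tt$day, 0)
  expect_equal(tt$day2, 0)
  tt2 <- temporal_terms(c(241, 241), c(2013, 2013))
  expect_equal(tt2$day[1], tt2$day[2])
  expect_equal(tt2$day, (241 - 194) / 47 * c(1, 1))
  expect_equal(tt2$day3, tt2$day^3)
})

test_that("the covariate table is complete and orthogonal where residualized", {
  cov <- default_covariates()
  need <- c("year", "day", "day2", "day3", "area", "sex", "translocated",
            "mcl_resid", "density_resid", "slope", "roughness_resid",
            "wash_pct", "minor_roads", "major_roads", "fencing",
            "burrows_resid", "ndvi_start_resid", "ndvi_active", "ndvi_32",
            "ndvi_16", "shrub_pct", "tmax_active", "tmax_32", "tmax_16",
            "rain_winter_resid", "rain_active", "rain_32_cat", "rain_16_cat",
            "offset_log_interval", "is_acm")
  expect_true(all(need %in% names(cov)))
  # residualized columns are orthogonal to their conditioning indicators
  Zsex <- model.matrix(~ sex - 1, cov)
  for (col in c("mcl_resid", "roughness_resid", "density_resid"))
    expect_lt(max(abs(crossprod(Zsex, cov[[col]]))), 1e-6)
  Zyr <- model.matrix(~ year - 1, cov)
  for (col in c("ndvi_start_resid", "rain_winter_resid"))
    expect_lt(max(abs(crossprod(Zyr, cov[[col]]))), 1e-6)
  # categorical levels ordered with the model reference levels first
  expect_equal(levels(cov$sex), c("male", "female", "subadult"))
  expect_equal(levels(cov$rain_32_cat), c("low", "medium", "high"))
  expect_true(all(sort(unique(cov$is_acm)) %in% 0:1))
})
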