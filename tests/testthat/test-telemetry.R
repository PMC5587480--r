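test_that("retention rules reproduce hand-worked cases", {
  # weekly in-burrow June fixes: all retained
  e1 <- toy_encounters(dates = c("2014-06-01", "2014-06-08", "2014-06-15"))
  expect_equal(nrow(filter_encounters(e1)), 3L)

  # 20-day gap: neither encounter can pair, both dropped
  e2 <- toy_encounters(dates = c("2014-06-01", "2014-06-21"))
  expect_equal(nrow(filter_encounters(e2)), 0L)

  # an April fix is excluded by the month rule even in a valid chain
  e3 <- toy_encounters(dates = c("2014-04-28", "2014-05-05", "2014-05-12"))
  f3 <- filter_encounters(e3)
  expect_equal(format(min(f3$date), "%m"), "05")
  expect_equal(nrow(f3), 2L)

  # burrow rule: in a burrow at t and at t-1 or t+1
  e4 <- toy_encounters(dates = c("2014-06-01", "2014-06-08", "2014-06-15"),
                       in_burrow = c(0L, 1L, 1L))
  expect_equal(nrow(filter_encounters(e4)), 2L)
  e5 <- toy_encounters(dates = c("2014-06-01", "2014-06-08", "2014-06-15"),
                       in_burrow = c(0L, 1L, 0L))
  expect_equal(nrow(filter_encounters(e5)), 0L)

  # year restriction
  e6 <- toy_encounters(dates = c("2012-06-01", "2012-06-08"))
  expect_equal(nrow(filter_encounters(e6, filter_rules(years = 2013:2015))), 0L)

  expect_error(filter_encounters(
    toy_encounters(dates = c("2014-06-01", "2014-06-01"))), "duplicate")
  expect_error(filter_rules(interval_min = 9, interval_max = 8), "interval")
})

test_that("filtering is idempotent and never adds rows", {
  for (seed in 1:20) {
    enc <- withr::with_seed(seed, {
      ids <- rep(sprintf("T%02d", 1:4), times = sample(3:12, 4, TRUE))
      do.call(rbind, lapply(split(ids, ids), function(g) {
        n <- length(g)
        toy_encounters(id = g[1],
                       dates = as.Date("2014-04-15") +
                         cumsum(sample(1:15, n, TRUE)),
                       in_burrow = rbinom(n, 1, 0.7))
      }))
    })
    once <- filter_encounters(enc)
    twice <- filter_encounters(once)
    expect_identical(once, twice)
    expect_lte(nrow(once), nrow(enc))
    expect_true(all(paste(once$tortoise_id, once$date) %in%
                      paste(enc$tortoise_id, enc$date)))
  }
})

test_that("movement records carry exact geometry and offsets", {
  enc <- toy_encounters(dates = c("2014-06-01", "2014-06-08"),
                        x = c(0, 3), y = c(0, 4))
  ros <- data.frame(tortoise_id = "A", sex = "male")
  mv <- build_movements(enc, ros)
  expect_equal(nrow(mv), 1L)
  expect_equal(mv$distance_m, 5)
  expect_equal(mv$offset_log_interval, log(7))
  expect_equal(c(mv$midpoint_x_m, mv$midpoint_y_m), c(1.5, 2))
  expect_equal(mv$interval_days, 7L)
  expect_equal(mv$sex, "male")

  # zero displacement is a valid record
  enc0 <- toy_encounters(dates = c("2014-06-01", "2014-06-07"),
                         x = c(10, 10), y = c(-2, -2))
  expect_equal(build_movements(enc0, ros)$distance_m, 0)

  expect_error(build_movements(enc, data.frame(tortoise_id = "B", sex = "male")),
               "A")
})

test_that("distances are invariant to translation and rotation", {
  enc <- withr::with_seed(42, toy_encounters(
    dates = as.Date("2014-06-01") + cumsum(sample(5:8, 9, TRUE)),
    x = rnorm(9, 0, 60), y = rnorm(9, 0, 60)))
  ros <- data.frame(tortoise_id = "A", sex = "female")
  d0 <- build_movements(enc, ros)$distance_m
  th <- 0.7
  enc2 <- enc
  enc2$x_m <- 1000 + enc$x_m * cos(th) - enc$y_m * sin(th)
  enc2$y_m <- -500 + enc$x_m * sin(th) + enc$y_m * cos(th)
  expect_equal(build_movements(enc2, ros)$distance_m, d0, tolerance = 1e-10)
})

test_that("every movement respects the interval rule and matches a truth step", {
  mv <- default_movements()
  expect_true(all(mv$interval_days >= 5 & mv$interval_days <= 8))
  expect_equal(mv$offset_log_interval, log(mv$interval_days))
  ds <- default_dataset()
  key_m <- paste(mv$tortoise_id, mv$t_start, mv$t_end)
  key_t <- paste(ds$truth$steps$tortoise_id, ds$truth$steps$t_start,
                 ds$truth$steps$t_end)
  expect_true(all(key_m %in% key_t))
})

test_that("distance summaries use linear-interpolation order statistics", {
  mk <- function(d) {
    mv <- data.frame(tortoise_id = "A", year = 2014, distance_m = d)
    summarize_distances(mv)
  }
  s <- mk(1:5)
  expect_equal(s$median_m, 3)
  expect_equal(s$iqr_m, c(2, 4))
  s1 <- mk(7)
  expect_equal(s1$median_m, 7)
  expect_equal(s1$iqr_m, c(7, 7))
  s0 <- summarize_distances(NULL)
  expect_equal(s0$n, 0L)
  expect_true(is.na(s0$median_m))
  # synthetic default lands at the within-center scale
  sd <- summarize_distances(default_movements())
  expect_gt(sd$median_m, 1)
  expect_lt(sd$median_m, 30)
})
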