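test_that("first-stage candidates respect window exclusivity and the core", {
  cfg <- stage1_config()
  for (g in names(cfg)) {
    specs <- stage1_candidates(g, cfg)
    for (sp in specs) {
      expect_true(all(temporal_core_terms() %in% sp$fixed_terms))
      vars <- unique(unlist(strsplit(sp$fixed_terms, ":", fixed = TRUE)))
      # never mix 16- and 32-day windows of the same quantity
      expect_false(any(grepl("_16", vars)) && any(grepl("_32", vars)))
    }
  }
  ndvi_specs <- stage1_candidates("vegetation", cfg)
  expect_false(any(vapply(ndvi_specs, function(sp)
    all(c("ndvi_16", "ndvi_32") %in% sp$fixed_terms), logical(1))))
  expect_error(stage1_candidates("geology", cfg), "unknown")
})

test_that("all-subsets enumeration of three covariates yields seven specs", {
  cfg <- list(landscape = list("a", "b", "c", c("a", "b"), c("a", "c"),
                               c("b", "c"), c("a", "b", "c")))
  specs <- stage1_candidates("landscape", cfg)
  expect_length(specs, 7L)
  expect_true(all(vapply(specs, function(sp)
    all(temporal_core_terms() %in% sp$fixed_terms), logical(1))))
})

test_that("the second-stage set has the prescribed combinatorial size", {
  w4 <- list(individual = c("sex", "sex:day"),
             landscape = c("fencing", "minor_roads"),
             vegetation = c("ndvi_16", "ndvi_16:day"),
             weather = c("tmax_32", "rain_32_cat", "tmax_32:rain_32_cat"))
  s4 <- stage2_set(w4)
  expect_length(s4, 17L)
  tags <- vapply(s4, `[[`, "", "group_tag")
  expect_equal(sum(tags == "constant"), 1L)
  expect_equal(sum(tags == "temporal"), 1L)
  expect_equal(sum(tags %in% names(w4)), 4L)
  expect_equal(sum(tags == "combination"), 11L)
  # shared temporal terms deduplicate in unions
  full <- s4[[length(s4)]]
  expect_equal(anyDuplicated(full$fixed_terms), 0L)

  expect_length(stage2_set(w4[c("individual", "weather")]), 5L)
  expect_length(stage2_set(w4["landscape"]), 3L)
  for (g in 1:4)
    expect_length(stage2_set(w4[seq_len(g)]), 2 + g + (2^g - 1 - g))
  expect_error(stage2_set(unname(w4)), "named")
})

test_that("BIC ranking and weights follow the exponential-difference rule", {
  cs <- rank_and_weight(c(100, 102, 104))
  expect_equal(cs$delta_bic, c(0, 2, 4))
  expect_equal(cs$weight, c(0.665, 0.245, 0.090), tolerance = 1e-3)
  expect_equal(sum(cs$weight), 1)
  # invariant to adding a constant to every BIC
  cs2 <- rank_and_weight(c(100, 102, 104) + 777)
  expect_equal(cs2$weight, cs$weight)
  # equal-BIC models split the weight
  expect_equal(rank_and_weight(c(50, 50))$weight, c(0.5, 0.5))
})

test_that("ranking of fitted candidates is stable and weight-normalized", {
  fits <- list(
    fake_fit("B", c("(Intercept)" = 0.2), c("(Intercept)" = 0.1), 102),
    fake_fit("A", c("(Intercept)" = 0.1), c("(Intercept)" = 0.1), 100),
    fake_fit("C", c("(Intercept)" = 0.0), c("(Intercept)" = 0.1), 100))
  cs <- rank_and_weight(fits)
  # tie on BIC breaks by label after K
  expect_equal(cs$label, c("A", "C", "B"))
  expect_equal(cs$delta_bic[1], 0)
  expect_equal(sum(cs$weight), 1, tolerance = 1e-9)
})

test_that("model averaging matches hand-computed identities", {
  # single model: averaging is the identity
  one <- rank_and_weight(list(
    fake_fit("m", c("(Intercept)" = -1, x = 2), c("(Intercept)" = 0.5, x = 0.4),
             100, terms = "x")))
  avg1 <- model_average(one)
  expect_false(attr(avg1, "averaged"))   # weight 1 >= 0.95 rule
  expect_equal(avg1$estimate, c(-1, 2))

  # two equally weighted models, theta 1 and 3, zero variance
  two <- rank_and_weight(list(
    fake_fit("m1", c(x = 1), c(x = 0), 100, terms = "x"),
    fake_fit("m2", c(x = 3), c(x = 0), 100, terms = "x")))
  avg2 <- model_average(two, top_weight_rule = 1.01)
  expect_equal(avg2$estimate[avg2$term == "x"], 2)
  expect_equal(avg2$se_uncond[avg2$term == "x"], 1)
  expect_equal(avg2$ci_lo[avg2$term == "x"], 2 - 1.96, tolerance = 1e-3)

  # full averaging shrinks a covariate present only in a w = 0.2 model
  delta <- 2 * log(4)  # weight ratio 4:1
  shr <- rank_and_weight(list(
    fake_fit("big", c(y = 1), c(y = 0), 100, terms = "y"),
    fake_fit("small", c(y = 1, z = 5), c(y = 0, z = 0), 100 + delta,
             terms = c("y", "z"))))
  expect_equal(shr$weight, c(0.8, 0.2), tolerance = 1e-9)
  avg3 <- model_average(shr, top_weight_rule = 1.01)
  expect_equal(avg3$estimate[avg3$term == "z"], 1, tolerance = 1e-9)
  # conditional averaging keeps the within-model value
  avg3c <- model_average(shr, conditional = TRUE, top_weight_rule = 1.01)
  expect_equal(avg3c$estimate[avg3c$term == "z"], 5, tolerance = 1e-9)
  # predictive flag: CI excluding zero
  expect_equal(avg3$predictive, avg3$ci_lo > 0 | avg3$ci_hi < 0)
})

test_that("scenario prediction inverts the logit at the linear predictor", {
  f <- fake_fit("m", c("(Intercept)" = 0, fencing = 0.8),
                c("(Intercept)" = 0.1, fencing = 0.2), 100,
                terms = "fencing")
  nd <- data.frame(fencing = c(0, 1), offset_log_interval = 0)
  pr <- predict_scenarios(f, nd)
  expect_equal(pr$prob[1], 0.5)
  expect_equal(pr$prob[2], plogis(0.8))
  expect_true(all(pr$prob_lo <= pr$prob & pr$prob <= pr$prob_hi))

  f2 <- fake_fit("icpt", c("(Intercept)" = -2.36), c("(Intercept)" = 0.14),
                 100, terms = character(0))
  nd2 <- data.frame(offset_log_interval = 0)
  expect_equal(predict_scenarios(f2, nd2)$prob, plogis(-2.36),
               tolerance = 1e-12)
  expect_equal(round(predict_scenarios(f2, nd2)$prob, 3), 0.086)

  expect_error(predict_scenarios(f, data.frame(offset_log_interval = 0)),
               "lacks")
})

test_that("fence and road effects propagate through fitted predictions", {
  fit <- default_truth_fit()
  cov <- default_covariates()
  ref <- as.data.frame(cov)[1, ]
  for (nm in names(ref)) {
    if (is.factor(cov[[nm]])) ref[[nm]] <- factor(levels(cov[[nm]])[1],
                                                  levels(cov[[nm]]))
    else if (is.numeric(cov[[nm]])) ref[[nm]] <- mean(cov[[nm]])
  }
  ref$offset_log_interval <- log(7)
  nd <- rbind(transform(ref, fencing = 0, minor_roads = 0),
              transform(ref, fencing = 1, minor_roads = 0),
              transform(ref, fencing = 0, minor_roads = 1))
  pr <- predict_scenarios(fit, nd)
  expect_gt(pr$prob[2], pr$prob[1])  # positive fence effect
  expect_lt(pr$prob[3], pr$prob[1])  # negative minor-road effect
  expect_true(all(pr$prob > 0 & pr$prob < 1))
})
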