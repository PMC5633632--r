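test_that("2-SD hazard ratios and their intervals are algebraically exact", {
  b <- small_cohort()
  iv <- standardize_2sd(build_quiet(b), "one_month_fge")
  f <- fit_frailty(iv, ~ one_month_fge + age_years, random = "none")
  h <- hr_per_2sd(f, "one_month_fge")
  z <- qnorm(0.95)
  expect_equal(h$hr, exp(h$beta))
  expect_equal(h$ci_low, exp(h$beta - z * h$se))
  expect_equal(h$ci_high, exp(h$beta + z * h$se))
  # back-calculating the SE from the CI is the exact inverse
  expect_equal((log(h$ci_high) - log(h$ci_low)) / (2 * z), h$se)
  expect_error(hr_per_2sd(f, "ghost"), class = "matchrisk_validation_error")
})

test_that("hazard-ratio curves are normalized at the reference", {
  b <- small_cohort()
  iv <- standardize_2sd(build_quiet(b), "one_month_fge")
  f <- fit_frailty(iv, ~ twelve_month_matches + one_month_fge,
                   random = "none")
  ref <- 15
  cv <- hr_curve(f, "twelve_month_matches", grid = c(5, 10, ref, 25),
                 ref = ref)
  i <- which(cv$x == ref)
  expect_equal(cv$hr[i], 1)
  expect_equal(cv$ci_low[i], 1)
  expect_equal(cv$ci_high[i], 1)
  # a linear positive effect gives a strictly increasing curve
  if (f$coefficients[["twelve_month_matches"]] > 0) {
    expect_true(all(diff(cv$hr) > 0))
  } else {
    expect_true(all(diff(cv$hr) < 0))
  }
  expect_warning(hr_curve(f, "twelve_month_matches", grid = c(0, 500)),
                 "extrapolation")
  p <- autoplot(cv)
  expect_s3_class(p, "ggplot")
})

test_that("polynomial bases predict with training centring", {
  x <- c(1, 5, 9, 14, 30)
  pb <- poly_c(x, 3)
  expect_equal(dim(pb), c(5L, 3L))
  expect_equal(unclass(pb[, 2]), ((x - mean(x)) / sd(x))^2,
               ignore_attr = TRUE)
  expect_error(poly_c(x, 4), class = "matchrisk_validation_error")
  # model.matrix on new data reuses the training centre/scale
  d <- data.frame(x = x)
  mf <- model.frame(~ poly_c(x, 2), d)
  tt <- attr(mf, "terms")
  X2 <- model.matrix(delete.response(tt),
                     model.frame(delete.response(tt), data.frame(x = c(2, 7))))
  expect_equal(X2[, 2], (c(2, 7) - mean(x)) / sd(x), ignore_attr = TRUE)
})

test_that("a constrained polynomial search returns the trivial table", {
  b <- small_cohort()
  iv <- build_quiet(b)
  ps <- polynomial_select(iv, "twelve_month_matches", max_degree = 1)
  expect_equal(ps$degree, 1L)
  expect_equal(nrow(ps$table), 1L)
})

test_that("quartile interactions recover attenuation and flag empty strata", {
  # attenuated top quartile: within-Q4 effect = 0.78 x the Q1 effect
  cfg_att <- sim_config(
    n_teams = 10, players_per_team = 30, n_seasons = 2,
    hr_2sd = c(age = 1, height = 1, mass = 1, prev_injury = 1,
               one_month_fge = 1.25),
    hr_position_forward = 1, twelve_month_coefs = c(0, 0, 0),
    sigma2_team = 0, sigma2_player = 0,
    interaction_hr_ratio = c(1, 1, 1, 0.78)
  )
  cfg_null <- utils::modifyList(cfg_att,
                                list(interaction_hr_ratio = c(1, 1, 1, 1)))
  class(cfg_null) <- class(cfg_att)
  run_one <- function(cfg, seed) {
    b <- simulate_cohort(cfg, seed = seed)
    iv <- standardize_2sd(build_quiet(b), "one_month_fge")
    iv$twelve_month_quartile <- assign_quartile(iv$twelve_month_matches,
                                                breaks = c(12, 22, 29))
    interaction_fit(iv, exposure = "one_month_fge", random = "none")
  }
  q4 <- vapply(1:4, function(s) {
    tb <- run_one(cfg_att, s)$table
    tb$hr_ratio[tb$quartile == "Q4"]
  }, numeric(1))
  expect_gt(mean(q4), 0.55)
  expect_lt(mean(q4), 1.00)

  q4n <- vapply(11:14, function(s) {
    tb <- run_one(cfg_null, s)$table
    tb$hr_ratio[tb$quartile == "Q4"]
  }, numeric(1))
  expect_gt(mean(q4n), 0.80)
  expect_lt(mean(q4n), 1.25)

  # a quartile stratum without events is a hard error
  b <- simulate_cohort(sim_config(n_teams = 3, players_per_team = 8,
                                  n_seasons = 1), seed = 1)
  iv <- build_quiet(b)
  iv$twelve_month_quartile <- factor(
    ifelse(iv$event, "Q1", sample(c("Q1", "Q2"), nrow(iv), replace = TRUE)),
    levels = c("Q1", "Q2")
  )
  expect_error(interaction_fit(iv, exposure = "one_month_fge",
                               random = "none"),
               "no events", class = "matchrisk_validation_error")
})

test_that("variance tests report boundary-aware statistics", {
  b <- small_cohort()
  iv <- standardize_2sd(build_quiet(b), "one_month_fge")
  f <- fit_frailty(iv, ~ one_month_fge, random = "player")
  vt <- variance_test(f, "player")
  expect_true(vt$lr_statistic >= 0)
  expect_true(vt$lr_p > 0 && vt$lr_p <= 0.5 + 1e-9)
  if (!is.na(vt$wald_statistic)) {
    expect_equal(vt$wald_p, pnorm(vt$wald_statistic, lower.tail = FALSE))
  }
  expect_error(variance_test(f, "team"), class = "matchrisk_validation_error")
})

test_that("model comparison flags follow the documented conventions", {
  b <- small_cohort()
  iv <- standardize_2sd(build_quiet(b), "one_month_fge")
  f0 <- fit_frailty(iv, ~ one_month_fge, random = "none")
  fs <- fit_frailty(iv, ~ one_month_fge, random = "player",
                    control = frailty_control(variance_se = FALSE))
  cmp <- compare_models(f0, fs)
  expect_equal(cmp$table$AIC, -2 * cmp$table$logLik + 2 * cmp$table$df)
  expect_equal(cmp$table$BIC,
               -2 * cmp$table$logLik + cmp$table$df * log(f0$n_events))
  # a model compared with itself: zero deltas and the p = 0.5 convention
  self <- compare_models(a = f0, b = f0)
  expect_equal(self$tests$lr_statistic, 0)
  expect_equal(self$tests$p, 0.5)
  expect_equal(self$tests$delta_AIC, 0)
  # fits on different data are refused
  other <- fit_frailty(iv[-(1:5), ], ~ one_month_fge, random = "none")
  expect_error(compare_models(f0, other),
               class = "matchrisk_validation_error")
})
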