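test_that("partial likelihood matches exhaustive risk-set enumeration", {
  # registry fixtures with known closed forms
  b <- make_fixture("two_players_one_injury")
  iv <- build_quiet(b, covariate_update = "interval_end")
  expect_equal(partial_loglik(iv$duration_hours, iv$event, rep(0, nrow(iv))),
               attr(b, "expected")$null_pll)

  tb <- make_fixture("tie_break")
  ivt <- build_quiet(tb, covariate_update = "interval_end")
  exp <- attr(tb, "expected")
  expect_equal(sort(ivt$duration_hours[ivt$event]),
               rep(exp$tied_duration, 2))
  eta0 <- rep(0, nrow(ivt))
  expect_equal(partial_loglik(ivt$duration_hours, ivt$event, eta0,
                              ties = "breslow"), exp$null_pll_breslow)
  expect_equal(partial_loglik(ivt$duration_hours, ivt$event, eta0,
                              ties = "efron"), exp$null_pll_efron)
  # the Efron-Breslow gap is the analytic two-event tie correction:
  # -log(S) - log(S - Sd/2) vs -2 log(S)
  S <- 3; Sd <- 2
  expect_equal(exp$null_pll_efron - exp$null_pll_breslow,
               (-log(S) - log(S - Sd / 2)) - (-2 * log(S)))

  # random small problems, with and without delayed entry, both tie methods
  for (s in 1:25) {
    d <- random_segments(n = sample(5:14, 1), seed = s)
    for (ties in c("efron", "breslow")) {
      expect_equal(
        partial_loglik(d$stop, d$event, d$eta, ties = ties, start = d$start),
        oracle_pll(d$stop, d$event, d$eta, ties = ties, start = d$start),
        tolerance = 1e-10, label = sprintf("seed %d %s", s, ties)
      )
    }
  }

  # null risk-set size form: -log(n at risk)
  expect_equal(partial_loglik(c(1, 2, 3), c(TRUE, FALSE, FALSE), rep(0, 3)),
               -log(3))
})

test_that("the Cox reduction reproduces survival::coxph exactly", {
  skip_if_not_installed("survival")
  library(survival)
  b <- small_cohort()
  iv <- standardize_2sd(build_quiet(b),
                        c("age_years", "one_month_fge"))
  f <- fit_frailty(iv, ~ age_years + position + one_month_fge,
                   random = "none")
  cp <- coxph(Surv(gap_start_hours, gap_stop_hours, event) ~
                age_years + position + one_month_fge,
              data = iv, ties = "efron")
  expect_equal(unname(f$coefficients), unname(coef(cp)), tolerance = 1e-7)
  expect_equal(unname(f$loglik[["partial"]]), cp$loglik[2])
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(cp)))), tolerance = 1e-6)

  fb <- fit_frailty(iv, ~ age_years + one_month_fge, random = "none",
                    ties = "breslow")
  cb <- coxph(Surv(gap_start_hours, gap_stop_hours, event) ~
                age_years + one_month_fge, data = iv, ties = "breslow")
  expect_equal(unname(fb$coefficients), unname(coef(cb)), tolerance = 1e-7)
})

test_that("the penalized mode matches coxph gaussian frailty at fixed theta", {
  skip_if_not_installed("survival")
  library(survival)
  b <- small_cohort()
  iv <- standardize_2sd(build_quiet(b), "one_month_fge")
  f <- fit_frailty(iv, ~ one_month_fge, random = "player",
                   control = frailty_control(fix_variance = c(player = 0.3),
                                             variance_se = FALSE))
  cp <- coxph(Surv(gap_start_hours, gap_stop_hours, event) ~ one_month_fge +
                frailty.gaussian(player_id, theta = 0.3, sparse = FALSE),
              data = iv, ties = "efron")
  expect_equal(unname(f$coefficients), unname(coef(cp)[1]),
               tolerance = 1e-6)
})

test_that("nesting identities hold in the zero-variance limits", {
  b <- small_cohort()
  iv <- standardize_2sd(build_quiet(b), c("age_years", "one_month_fge"))
  form <- ~ age_years + one_month_fge
  f0 <- fit_frailty(iv, form, random = "none")
  fz <- fit_frailty(iv, form, random = "team_player",
                    control = frailty_control(
                      fix_variance = c(team = 0, player = 0),
                      variance_se = FALSE))
  expect_equal(fz$coefficients, f0$coefficients, tolerance = 1e-8)
  expect_equal(fz$loglik[["integrated"]], f0$loglik[["integrated"]],
               tolerance = 1e-10)

  fs <- fit_frailty(iv, form, random = "player",
                    control = frailty_control(variance_se = FALSE))
  ft <- fit_frailty(iv, form, random = "team_player",
                    control = frailty_control(fix_variance = c(team = 0),
                                              variance_se = FALSE))
  expect_equal(ft$coefficients, fs$coefficients, tolerance = 1e-6)
  expect_equal(ft$sigma2[["player"]], fs$sigma2[["player"]],
               tolerance = 1e-3)
})

test_that("duration units do not affect estimates", {
  b <- small_cohort()
  iv <- standardize_2sd(build_quiet(b), "one_month_fge")
  f1 <- fit_frailty(iv, ~ one_month_fge, random = "none")
  ivm <- iv
  ivm$gap_start_hours <- ivm$gap_start_hours * 60   # hours -> minutes
  ivm$gap_stop_hours <- ivm$gap_stop_hours * 60
  f2 <- fit_frailty(ivm, ~ one_month_fge, random = "none")
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
  expect_equal(f1$loglik[["partial"]], f2$loglik[["partial"]],
               tolerance = 1e-9)
})

test_that("Newton iterations increase the penalized likelihood monotonically", {
  b <- small_cohort()
  iv <- standardize_2sd(build_quiet(b), "one_month_fge")
  f <- fit_frailty(iv, ~ one_month_fge, random = "player",
                   control = frailty_control(variance_se = FALSE))
  tr <- f$convergence$ppl_trace
  expect_true(all(diff(tr) > -1e-8 * (abs(tr[-length(tr)]) + 1)))
  expect_lt(f$convergence$grad_norm, 1e-3)
})

test_that("degenerate specifications behave as documented", {
  b <- small_cohort()
  iv <- build_quiet(b)
  # null model: no covariates, no random effects
  f <- fit_frailty(iv, ~ 1, random = "none")
  expect_length(f$coefficients, 0)
  expect_equal(f$loglik[["partial"]],
               partial_loglik(iv$gap_stop_hours, iv$event,
                              rep(0, nrow(iv)), start = iv$gap_start_hours))
  # collinear designs are rejected with a clear message
  iv$dup <- iv$one_month_fge
  expect_error(
    fit_frailty(iv, ~ one_month_fge + dup, random = "none"),
    "collinear", class = "matchrisk_validation_error"
  )
  # a team effect needs at least two teams
  one_team <- iv[iv$team_id == iv$team_id[1], ]
  expect_error(
    fit_frailty(one_team, ~ one_month_fge, random = "team_player"),
    "2 teams", class = "matchrisk_validation_error"
  )
})
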