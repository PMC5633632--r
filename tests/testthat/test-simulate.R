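test_that("identical configuration and seed give identical cohorts", {
  cfg <- sim_config(n_teams = 3, players_per_team = 8, n_seasons = 1)
  b1 <- simulate_cohort(cfg, seed = 9)
  b2 <- simulate_cohort(cfg, seed = 9)
  for (tab in c("players", "matches", "training", "injuries")) {
    expect_identical(as.data.frame(b1[[tab]]), as.data.frame(b2[[tab]]),
                     label = tab)
  }
  b3 <- simulate_cohort(cfg, seed = 10)
  expect_false(identical(as.data.frame(b1$matches),
                         as.data.frame(b3$matches)))
})

test_that("generated cohorts always satisfy the validation contract", {
  for (s in c(1, 7)) {
    b <- simulate_cohort(sim_config(n_teams = 3, players_per_team = 10,
                                    n_seasons = 2), seed = s)
    expect_s3_class(b, "cohort_bundle")   # constructor already validated
    expect_silent(validate_cohort(b))
    # minutes and anthropometrics inside their invariant ranges
    expect_true(all(b$matches$minutes >= 0 & b$matches$minutes <= 100))
    expect_true(all(b$injuries$return_date > b$injuries$injury_date))
  }
})

test_that("config validation rejects impossible parameterizations", {
  expect_error(sim_config(sigma2_player = -1),
               class = "matchrisk_validation_error")
  expect_error(sim_config(minutes_full = 0.9, minutes_bench = 0.3),
               class = "matchrisk_validation_error")
  expect_error(sim_config(study_start = as.Date("2013-09-03")),
               class = "matchrisk_validation_error")
  expect_error(sim_config(interaction_hr_ratio = c(1, 1)),
               class = "matchrisk_validation_error")
  expect_error(make_fixture("nope"))
})

test_that("null-effect cohorts produce Poisson event counts in exposure", {
  cfg <- sim_config(
    n_teams = 6, players_per_team = 15, n_seasons = 2,
    hr_2sd = c(age = 1, height = 1, mass = 1, prev_injury = 1,
               one_month_fge = 1),
    hr_position_forward = 1, twelve_month_coefs = c(0, 0, 0),
    sigma2_team = 0, sigma2_player = 0
  )
  for (s in 1:2) {
    b <- simulate_cohort(cfg, seed = s)
    iv <- build_quiet(b, covariate_update = "interval_end",
                      drop_zero_exposure = FALSE)
    hours <- tapply(iv$duration_hours, iv$player_id, sum)
    counts <- tapply(iv$event, iv$player_id, sum)
    mu <- cfg$baseline_hazard * hours
    x2 <- sum((counts - mu)^2 / mu)
    p <- pchisq(x2, df = length(mu), lower.tail = FALSE)
    expect_gt(p, 0.01)
    # and the total count is within Poisson fluctuation of its expectation
    expect_lt(abs(sum(counts) - sum(mu)) / sqrt(sum(mu)), 4)
  }
})

test_that("player frailty induces overdispersion of injury counts", {
  base <- list(
    n_teams = 6, players_per_team = 15, n_seasons = 2,
    hr_2sd = c(age = 1, height = 1, mass = 1, prev_injury = 1,
               one_month_fge = 1),
    hr_position_forward = 1, twelve_month_coefs = c(0, 0, 0),
    sigma2_team = 0
  )
  disp <- function(sigma2) {
    cfg <- do.call(sim_config, c(base, list(sigma2_player = sigma2)))
    b <- simulate_cohort(cfg, seed = 5)
    counts <- table(factor(b$injuries$player_id,
                           levels = b$players$player_id))
    var(as.numeric(counts)) / mean(as.numeric(counts))
  }
  expect_gt(disp(1.0), 1.5)
  expect_lt(disp(0), 1.4)
})

test_that("default workload distributions match the intended cohort profile", {
  b <- simulate_cohort(sim_config(), seed = 1)
  # evaluate on in-season Mondays spread over the study
  at <- tidyr::expand_grid(
    player_id = b$players$player_id,
    eval_date = as.Date("2013-09-02") + 7 * c(60, 70, 120) + 4
  )
  sn <- exposure_snapshots(b$matches, at)
  expect_gt(mean(sn$twelve_month_matches), 16.8)
  expect_lt(mean(sn$twelve_month_matches), 20.8)
  expect_gt(sd(sn$twelve_month_matches), 7.6)
  expect_lt(sd(sn$twelve_month_matches), 11.6)
  expect_lte(max(sn$twelve_month_matches), 45)
  expect_gt(mean(sn$one_month_fge), 1.2)
  expect_lt(mean(sn$one_month_fge), 2.2)
  expect_gt(sd(sn$one_month_fge), 0.9)
  expect_lt(sd(sn$one_month_fge), 1.9)
  # anthropometrics near their nominal moments
  expect_equal(mean(b$players$height_cm), 186, tolerance = 0.02)
  expect_equal(mean(b$players$mass_kg), 102, tolerance = 0.03)
})

test_that("the hazard's covariates equal the pipeline's segment covariates", {
  cfg <- sim_config(n_teams = 4, players_per_team = 10, n_seasons = 2)
  b <- simulate_cohort(cfg, seed = 3, detail = TRUE)
  pn <- attr(b, "truth")$panel
  seg <- build_quiet(b, drop_zero_exposure = FALSE)
  wk <- as.integer((seg$start_date + 1 - cfg$study_start) / 7) + 1L
  pidx <- match(seg$player_id, b$players$player_id)
  ok <- wk >= 1 & wk <= ncol(pn$fge1)
  gen_fge <- pn$fge1[cbind(pidx[ok], wk[ok])]
  gen_cnt <- pn$cnt12[cbind(pidx[ok], wk[ok])]
  expect_equal(seg$one_month_fge[ok], gen_fge, tolerance = 1e-12)
  expect_equal(as.numeric(seg$twelve_month_matches[ok]), gen_cnt,
               tolerance = 1e-12)
})
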