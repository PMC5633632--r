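mk_matches <- function(dates, minutes, id = "p1") {
  tibble::tibble(player_id = id, match_date = as.Date(dates),
                 minutes = minutes)
}

test_that("12-month exposure counts involvements of at least 20 minutes", {
  d0 <- as.Date("2020-06-01")
  m <- mk_matches(d0 - c(10, 20, 30), c(19, 20, 80))
  expect_identical(twelve_month_exposure(m, "p1", d0), 2L)
  # fge mode has no minutes filter
  expect_equal(twelve_month_exposure(m, "p1", d0, mode = "fge"),
               (19 + 20 + 80) / 80)
  # empty window
  expect_identical(twelve_month_exposure(m, "p1", d0 - 400), 0L)
  # window is half-open: a match exactly 365 days back is excluded,
  # a match on the evaluation day included
  m2 <- mk_matches(c(d0 - 365, d0), c(80, 80))
  expect_identical(twelve_month_exposure(m2, "p1", d0), 1L)
  # 30 full matches in fge mode
  m3 <- mk_matches(d0 - seq_len(30), rep(80, 30))
  expect_equal(twelve_month_exposure(m3, "p1", d0, mode = "fge"), 30)
  # unknown player against a roster errors; without a roster it is 0 exposure
  roster <- tibble::tibble(player_id = "p1")
  expect_error(twelve_month_exposure(m, "p2", d0, players = roster),
               class = "matchrisk_referential_error")
  expect_identical(twelve_month_exposure(m, "p2", d0), 0L)
})

test_that("1-month FGE is minutes over the trailing 30 days divided by 80", {
  d0 <- as.Date("2020-06-01")
  expect_equal(one_month_fge(mk_matches(d0 - 5, 80), "p1", d0), 1)
  expect_equal(one_month_fge(mk_matches(d0 - c(3, 10, 17), c(60, 20, 80)),
                             "p1", d0), 2)
  expect_equal(one_month_fge(mk_matches(d0 - 31, 80), "p1", d0), 0)
})

test_that("quartile breakpoints follow the linear-interpolation rule", {
  expect_equal(quartile_breakpoints(1:40), c(10.75, 20.5, 30.25))
  expect_error(quartile_breakpoints(c(1, 2, 3)),
               class = "matchrisk_validation_error")
  expect_error(quartile_breakpoints(rep(7, 50)), "degenerate",
               class = "matchrisk_validation_error")
  # fixed breakpoints 12/22/29 reproduce the <12, 12-21, 22-28, >28 bins
  q <- assign_quartile(c(11, 12, 21, 22, 28, 29, 40), breaks = c(12, 22, 29))
  expect_equal(as.character(q), c("Q1", "Q2", "Q2", "Q3", "Q3", "Q4", "Q4"))
})

test_that("exposure hours combine match minutes and pro-rated training", {
  m <- mk_matches("2020-01-11", 80)
  tr <- tibble::tibble(team_id = "t1", week_start = as.Date("2020-01-06"),
                       hours = 10)
  # empty interval
  expect_equal(exposure_hours(m, tr, "p1", as.Date("2020-01-10"),
                              as.Date("2020-01-10"), "t1"), 0)
  # one 80-minute match plus one full training week
  expect_equal(exposure_hours(m, tr, "p1", as.Date("2020-01-05"),
                              as.Date("2020-01-12"), "t1"), 80 / 60 + 10)
  # part of a training week pro-rated by day overlap: Mon-Wed is 3/7 of 10 h
  expect_equal(exposure_hours(m[0, ], tr, "p1", as.Date("2020-01-05"),
                              as.Date("2020-01-08"), "t1"), 10 * 3 / 7)
  expect_error(exposure_hours(m, tr, "p1", as.Date("2020-01-12"),
                              as.Date("2020-01-10"), "t1"),
               class = "matchrisk_validation_error")
})

test_that("incidence rates are injuries per 1000 exposure hours", {
  inj <- tibble::tibble(season = rep(1L, 1), setting = "match")
  exp1 <- tibble::tibble(season = 1L, setting = "match", hours = 1000)
  expect_equal(incidence_rates(inj, exp1)$rate, 1)

  inj50 <- tibble::tibble(season = rep(1L, 50), setting = "match")
  exp582 <- tibble::tibble(season = 1L, setting = "match", hours = 582)
  expect_equal(round(incidence_rates(inj50, exp582)$rate, 1), 85.9)

  # zero injuries with positive hours is a zero rate
  none <- tibble::tibble(season = integer(0), setting = character(0))
  expect_equal(incidence_rates(none, exp1)$rate, 0)
  # zero hours is undefined
  exp0 <- tibble::tibble(season = 1L, setting = "match", hours = 0)
  expect_error(incidence_rates(inj, exp0),
               class = "matchrisk_validation_error")
  # mean +/- SD across seasons lives in the summary attribute
  inj2 <- tibble::tibble(season = c(1L, 1L, 2L), setting = "match")
  exph <- tibble::tibble(season = c(1L, 2L), setting = "match",
                         hours = c(100, 100))
  s <- attr(incidence_rates(inj2, exph), "summary")
  expect_equal(s$mean_rate, mean(c(20, 10)))
  expect_equal(s$sd_rate, sd(c(20, 10)))
})

test_that("window additivity and monotonicity hold on random fixtures", {
  d0 <- as.Date("2021-03-01")
  for (s in 1:20) {
    set.seed(s)
    n <- sample(3:25, 1)
    m <- mk_matches(d0 - sample(0:400, n, replace = FALSE),
                    sample(c(1:19, 20:80), n, replace = TRUE))
    # additivity: any split of the involvement list sums to the whole
    part <- runif(n) < 0.5
    whole <- twelve_month_exposure(m, "p1", d0, mode = "fge")
    expect_equal(twelve_month_exposure(m[part, ], "p1", d0, mode = "fge") +
                   twelve_month_exposure(m[!part, ], "p1", d0, mode = "fge"),
                 whole)
    # monotonicity: adding an in-window involvement never decreases exposure
    extra <- dplyr::bind_rows(m, mk_matches(d0 - 7, 35))
    expect_gte(twelve_month_exposure(extra, "p1", d0),
               twelve_month_exposure(m, "p1", d0))
    expect_gte(twelve_month_exposure(extra, "p1", d0, mode = "fge"), whole)
    # brute-force oracle for the snapshot values
    naive12 <- sum(m$minutes >= 20 & m$match_date > d0 - 365 &
                     m$match_date <= d0)
    naive1 <- sum(m$minutes[m$match_date > d0 - 30 & m$match_date <= d0]) / 80
    sn <- exposure_snapshots(m, tibble::tibble(player_id = "p1",
                                               eval_date = d0))
    expect_identical(sn$twelve_month_matches, as.integer(naive12))
    expect_equal(sn$one_month_fge, naive1)
    # count mode equals fge mode when every involvement is a full match
    full <- mk_matches(d0 - sample(0:300, 8), rep(80, 8))
    expect_equal(twelve_month_exposure(full, "p1", d0, mode = "fge"),
                 as.numeric(twelve_month_exposure(full, "p1", d0)))
  }
})
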