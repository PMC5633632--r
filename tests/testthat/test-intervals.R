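test_that("a hand-walked timeline yields the expected intervals", {
  entry <- as.Date("2020-01-06")
  exit <- as.Date("2020-06-01")
  players <- tibble::tibble(
    player_id = "A", team_id = "T1", birth_date = as.Date("1994-01-06"),
    height_cm = 185, mass_kg = 100, position = "forward",
    entry_date = entry, exit_date = exit
  )
  matches <- tibble::tibble(
    player_id = "A", team_id = "T1",
    match_date = as.Date(c("2020-01-18", "2020-02-22", "2020-04-18")),
    minutes = c(80, 80, 60)
  )
  injuries <- tibble::tibble(
    player_id = "A",
    injury_date = as.Date(c("2020-03-01", "2020-04-20")),
    return_date = as.Date(c("2020-03-15", "2020-05-01")),
    setting = "match", diagnosis_code = NA_character_
  )
  b <- cohort_bundle(players, matches,
                     tibble::tibble(team_id = character(0),
                                    week_start = as.Date(character()),
                                    hours = numeric(0)),
                     injuries)
  iv <- build_quiet(b, covariate_update = "interval_end",
                    drop_zero_exposure = FALSE)
  expect_equal(nrow(iv), 3L)
  expect_equal(iv$event, c(TRUE, TRUE, FALSE))
  expect_equal(iv$prev_injury_count, c(0L, 1L, 2L))
  expect_equal(iv$start_date, c(entry, as.Date("2020-03-15"),
                                as.Date("2020-05-01")))
  expect_equal(iv$end_date, c(injuries$injury_date, exit))
  # durations: two matches before injury 1; one 60-min match in interval 2
  expect_equal(iv$duration_hours, c(160 / 60, 60 / 60, 0))
  # age evaluated at the interval end
  expect_equal(iv$age_years[1],
               as.numeric(as.Date("2020-03-01") - players$birth_date) / 365.25)
})

test_that("no-event players yield exactly one censored interval", {
  b <- make_fixture("two_players_one_injury")
  iv <- build_quiet(b, covariate_update = "interval_end")
  bb <- iv[iv$player_id == "B", ]
  expect_equal(nrow(bb), 1L)
  expect_false(bb$event)
  expect_equal(iv$duration_hours[iv$player_id == "B"],
               attr(b, "expected")$durations[3])
})

test_that("zero 12-month exposure intervals are excluded and logged", {
  b <- make_fixture("zero_exposure_exclusion")
  expect_message(
    iv <- build_intervals(b, covariate_update = "interval_end"),
    "excluded 1"
  )
  exp <- attr(b, "expected")
  expect_equal(attr(iv, "n_excluded_zero_exposure"), exp$n_excluded)
  expect_equal(attr(iv, "n_excluded_events"), exp$n_excluded_events)
  expect_equal(nrow(iv), exp$n_intervals_kept)
  # the event count equals injuries minus excluded events
  expect_equal(sum(iv$event), nrow(b$injuries) - exp$n_excluded_events)
})

test_that("interval durations conserve total at-risk exposure", {
  b <- small_cohort()
  iv <- build_quiet(b, covariate_update = "interval_end",
                    drop_zero_exposure = FALSE, zero_duration_floor = 0)
  # per player: the sum of interval durations equals total exposure between
  # entry and exit minus hours inside injury-absence spells
  mt <- split(b$matches, b$matches$player_id)
  tr <- split(b$training, b$training$team_id)
  for (pid in sample(unique(iv$player_id), 8)) {
    p <- b$players[b$players$player_id == pid, ]
    total <- exposure_hours(mt[[pid]], tr[[p$team_id]], pid,
                            p$entry_date, p$exit_date, p$team_id)
    inj <- b$injuries[b$injuries$player_id == pid, ]
    absent <- 0
    if (nrow(inj)) {
      absent <- sum(vapply(seq_len(nrow(inj)), function(k) {
        exposure_hours(mt[[pid]], tr[[p$team_id]], pid,
                       inj$injury_date[k],
                       min(inj$return_date[k], p$exit_date), p$team_id)
      }, numeric(1)))
    }
    expect_equal(sum(iv$duration_hours[iv$player_id == pid]), total - absent,
                 tolerance = 1e-10, label = pid)
  }
  # intervals are chronologically contiguous apart from absence gaps:
  # every interval after the first starts at a return date
  for (pid in unique(iv$player_id)) {
    pv <- iv[iv$player_id == pid, ]
    if (nrow(pv) < 2) next
    inj <- b$injuries[b$injuries$player_id == pid, ]
    expect_equal(pv$start_date[-1],
                 sort(inj$return_date)[seq_len(nrow(pv) - 1)],
                 label = pid)
  }
})

test_that("weekly segments agree with whole-interval accounting", {
  b <- small_cohort()
  seg <- build_quiet(b, drop_zero_exposure = FALSE, zero_duration_floor = 0)
  ive <- build_quiet(b, covariate_update = "interval_end",
                     drop_zero_exposure = FALSE, zero_duration_floor = 0)
  # exposure hours per interval match between the two constructions
  agg <- tapply(seg$duration_hours, seg$interval_id, sum)
  cmp <- ive$duration_hours[match(as.integer(names(agg)), ive$interval_id)]
  expect_equal(as.numeric(agg), cmp, tolerance = 1e-10)
  # gap coordinates are contiguous within an interval
  for (id in sample(unique(seg$interval_id), 15)) {
    sg <- seg[seg$interval_id == id, ]
    sg <- sg[order(sg$gap_stop_hours), ]
    expect_equal(sg$gap_start_hours[-1], sg$gap_stop_hours[-nrow(sg)])
    expect_equal(sg$gap_start_hours[1], 0)
    # the event, if any, sits on the last segment
    if (any(sg$event)) expect_true(sg$event[nrow(sg)])
  }
  # event totals agree
  expect_equal(sum(seg$event), sum(ive$event))
})

test_that("2-SD standardization scales and reports correctly", {
  set.seed(1)
  d <- tibble::tibble(x = rnorm(200, 10, 1.6), y = rnorm(200))
  out <- standardize_2sd(d, c("x", "y"))
  expect_equal(mean(out$x), 0, tolerance = 1e-12)
  expect_equal(sd(out$x), 0.5, tolerance = 1e-12)
  rep <- scale_report(out)
  expect_equal(rep$variable, c("x", "y"))
  expect_equal(rep$two_sd[1], 2 * sd(d$x))
  # a unit change on the transformed scale is exactly 2 SDs
  expect_equal(diff(range(out$x)) * rep$two_sd[1], diff(range(d$x)))
  expect_error(standardize_2sd(tibble::tibble(z = rep(1, 5)), "z"),
               "zero SD", class = "matchrisk_validation_error")
  expect_error(standardize_2sd(d, "missing"),
               class = "matchrisk_validation_error")
})

test_that("calendar-days axis provides a log-exposure offset", {
  b <- small_cohort()
  iv <- build_quiet(b, covariate_update = "interval_end",
                    time_axis = "calendar_days")
  expect_true("log_exposure_offset" %in% names(iv))
  expect_equal(iv$duration_hours,
               as.numeric(iv$end_date - iv$start_date))
  f <- fit_frailty(iv, ~ one_month_fge, random = "none",
                   offset = "log_exposure_offset")
  expect_true(is.finite(f$loglik[["partial"]]))
})
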