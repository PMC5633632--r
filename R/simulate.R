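#' Configuration of the synthetic cohort generator
#'
#' Parameterises a multi-team, multi-season squad whose injury process is a
#' proportional-hazards model on the exposure-hour axis read forwards: each
#' week a player accrues match minutes and pro-rated team training hours, and
#' an injury occurs with hazard
#' `baseline_hazard * exp(x'beta + b_team + b_player)` per exposure hour,
#' with log-normal team and player frailties. Effect sizes are specified on
#' the reporting scale — hazard ratios per 2 SD together with the nominal
#' SDs — and converted to per-unit log-hazard coefficients internally; the
#' chronic-load (12-month match count) effect is a cubic on the raw count
#' centred at 19 matches, with defaults tracing a U-shape (elevated risk
#' below ~15 and above ~32 matches); the acute-load (1-month FGE) effect can
#' be attenuated per chronic-load quartile through `interaction_hr_ratio`.
#'
#' The default squad-selection and minutes mixture are calibrated so that
#' the simulated workload distributions resemble elite rugby union: mean
#' 12-month match exposure around 19 (SD ~9.6, range ~1–40) and mean 1-month
#' exposure around 1.7 FGE (SD ~1.6). A season is 38 weekly fixtures
#' (Saturdays) followed by a 14-week off-season with no training rows.
#'
#' @param n_teams,players_per_team,n_seasons cohort dimensions (defaults 12,
#'   45, 3).
#' @param study_start first Monday of the study (default 2013-09-02).
#' @param season_weeks fixture weeks per 52-week season-year.
#' @param p_play_shape Beta(shape1, shape2) distribution of each player's
#'   per-fixture selection probability (squad-role heterogeneity).
#' @param minutes_full,minutes_bench probability that a selected player plays
#'   the full 80 minutes / a 20–79-minute bench appearance (remainder:
#'   a 1–19-minute cameo).
#' @param train_mean,train_sd weekly team training hours, Normal truncated at
#'   0.
#' @param baseline_hazard injuries per exposure hour for a reference player.
#' @param hr_2sd,two_sd named vectors: hazard ratios per 2 SD and the
#'   corresponding 2-SD spans in raw units for age (years), height (cm),
#'   mass (kg), prev_injury (count) and one_month_fge (FGE).
#' @param hr_position_forward hazard ratio of forwards vs backs.
#' @param twelve_month_coefs cubic coefficients (u, u^2, u^3) of the
#'   log-hazard in u = 12-month match count − 19.
#' @param interaction_hr_ratio length-4 multipliers (HR scale, Q1 = 1) on
#'   the 2-SD acute-load hazard ratio within chronic-load quartiles.
#' @param quartile_breaks chronic-load quartile breakpoints used by the
#'   generator's interaction term.
#' @param sigma2_team,sigma2_player frailty variances on the log-hazard.
#' @param absence_meanlog,absence_sdlog,absence_min_days log-normal
#'   injury-absence duration (days), floored. Injury settings are labelled
#'   by the exposure piece (training week vs match) that generated the
#'   event; because the generative hazard is uniform per exposure hour, the
#'   match/training split of synthetic injuries follows exposure shares, not
#'   the much higher per-hour match risk seen in real surveillance data.
#' @param age_mean,age_sd,height_mean,height_sd,mass_mean,mass_sd,p_forward
#'   anthropometric distributions.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_teams = 12, players_per_team = 45, n_seasons = 3,
                       study_start = as.Date("2013-09-02"),
                       season_weeks = 38,
                       p_play_shape = c(1.19, 0.97),
                       minutes_full = 0.60, minutes_bench = 0.30,
                       train_mean = 10, train_sd = 1.5,
                       baseline_hazard = 0.002,
                       hr_2sd = c(age = 1.03, height = 1.05, mass = 1.02,
                                  prev_injury = 1.28, one_month_fge = 1.14),
                       two_sd = c(age = 8, height = 15, mass = 26,
                                  prev_injury = 6, one_month_fge = 3.2),
                       hr_position_forward = 0.91,
                       twelve_month_coefs = c(-0.01651, 0.001397, 1.657e-05),
                       interaction_hr_ratio = c(1, 1, 1, 1),
                       quartile_breaks = c(12, 22, 29),
                       sigma2_team = 0.05, sigma2_player = 0.2,
                       absence_meanlog = log(10), absence_sdlog = 0.7,
                       absence_min_days = 2,
                       age_mean = 26, age_sd = 4,
                       height_mean = 186, height_sd = 8,
                       mass_mean = 102, mass_sd = 13,
                       p_forward = 8 / 15) {
  cfg <- as.list(environment())
  if (sigma2_team < 0 || sigma2_player < 0) {
    stop_validation("frailty variances must be non-negative")
  }
  if (minutes_full + minutes_bench > 1 || minutes_full < 0 ||
      minutes_bench < 0) {
    stop_validation("minutes mixture probabilities must lie in [0, 1]")
  }
  if (as.POSIXlt(study_start)$wday != 1L) {
    stop_validation("study_start must be a Monday")
  }
  if (length(interaction_hr_ratio) != 4L || any(interaction_hr_ratio <= 0)) {
    stop_validation("interaction_hr_ratio must be 4 positive multipliers")
  }
  if (season_weeks < 1 || season_weeks > 52) {
    stop_validation("season_weeks must be in 1..52")
  }
  structure(cfg, class = c("sim_config", "list"))
}

#' Simulate a synthetic multi-team cohort
#'
#' Walks every player's calendar week by week, drawing squad selection,
#' minutes, training exposure and injuries from the generative model
#' described in [sim_config()], and returns the four cohort tables as a
#' validated `cohort_bundle`. Identical `(config, seed)` give identical
#' output; independent RNG streams are derived from the master seed per
#' component (roster, frailties, training, match/injury walk) so that e.g.
#' changing squad size does not perturb training hours.
#'
#' The returned bundle carries a `truth` attribute with the drawn frailties,
#' the per-unit log-hazard coefficients actually applied, and each player's
#' approximate at-risk exposure hours — the ground truth for parameter
#' recovery studies.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed.
#' @return a `cohort_bundle` with attribute `truth`.
#' @examples
#' b <- simulate_cohort(sim_config(n_teams = 3, players_per_team = 8,
#'                                 n_seasons = 1), seed = 1)
#' b
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1, detail = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  n_p <- cf$n_teams * cf$players_per_team
  # the study ends with the last fixture week of the final season: the
  # trailing off-season carries no exposure (no risk time) and would force
  # every censored interval to end on a zero acute-load date
  n_weeks <- (cf$n_seasons - 1L) * 52L + cf$season_weeks
  monday <- cf$study_start + (seq_len(n_weeks) - 1L) * 7L
  in_season <- ((seq_len(n_weeks) - 1L) %% 52L) < cf$season_weeks
  exit_date <- cf$study_start + n_weeks * 7L - 1L

  team_ids <- sprintf("T%02d", seq_len(cf$n_teams))
  player_ids <- sprintf("P%04d", seq_len(n_p))
  team_of <- rep(seq_len(cf$n_teams), each = cf$players_per_team)

  # roster stream
  set.seed(child_seed(seed, 1L))
  age0 <- pmin(pmax(rnorm(n_p, cf$age_mean, cf$age_sd), 18), 38)
  height <- pmin(pmax(rnorm(n_p, cf$height_mean, cf$height_sd), 150), 225)
  mass <- pmin(pmax(rnorm(n_p, cf$mass_mean, cf$mass_sd), 60), 160)
  forward <- runif(n_p) < cf$p_forward
  p_play <- rbeta(n_p, cf$p_play_shape[1], cf$p_play_shape[2])
  players <- tibble(
    player_id = player_ids, team_id = team_ids[team_of],
    birth_date = cf$study_start - round(age0 * 365.25),
    height_cm = round(height, 1), mass_kg = round(mass, 1),
    position = ifelse(forward, "forward", "back"),
    entry_date = cf$study_start, exit_date = exit_date
  )

  # frailty stream
  set.seed(child_seed(seed, 2L))
  b_team <- rnorm(cf$n_teams, 0, sqrt(cf$sigma2_team))
  b_player <- rnorm(n_p, 0, sqrt(cf$sigma2_player))

  # training stream: hours per team x week (0 in the off-season)
  set.seed(child_seed(seed, 3L))
  train_h <- matrix(0, cf$n_teams, n_weeks)
  train_h[, in_season] <- pmax(
    0, rnorm(cf$n_teams * sum(in_season), cf$train_mean, cf$train_sd))
  training <- tibble(
    team_id = rep(team_ids, times = sum(in_season)),
    week_start = rep(monday[in_season], each = cf$n_teams),
    hours = as.vector(train_h[, in_season])
  )
  training <- dplyr::arrange(training, .data$team_id, .data$week_start)

  # effect sizes on the per-unit log-hazard scale
  lb <- log(cf$hr_2sd) / cf$two_sd
  beta_age <- lb[["age"]]; beta_h <- lb[["height"]]; beta_m <- lb[["mass"]]
  beta_prev <- lb[["prev_injury"]]
  beta_pos <- log(cf$hr_position_forward)
  beta_1m_q <- (log(cf$hr_2sd[["one_month_fge"]]) +
                  log(cf$interaction_hr_ratio)) / cf$two_sd[["one_month_fge"]]
  cc <- cf$twelve_month_coefs

  # match/injury walk stream
  set.seed(child_seed(seed, 4L))
  M <- matrix(0, n_p, n_weeks)          # minutes played per player-week
  P20 <- matrix(FALSE, n_p, n_weeks)    # involvement of >= 20 min
  absent_until <- rep(cf$study_start - 1000L, n_p)  # first day back at risk
  prev_cnt <- integer(n_p)
  risk_hours <- numeric(n_p)
  inj_p <- integer(0); inj_d <- as.Date(character())
  inj_r <- as.Date(character()); inj_s <- character(0)
  if (detail) {
    panel <- list(fge1 = matrix(0, n_p, n_weeks), cnt12 = matrix(0, n_p, n_weeks),
                  hours = matrix(0, n_p, n_weeks), frac = matrix(0, n_p, n_weeks),
                  eta = matrix(0, n_p, n_weeks))
  }

  for (w in seq_len(n_weeks)) {
    mon <- monday[w]
    # at-risk fraction of the week (players rejoin mid-week after absence)
    frac <- pmin(7, pmax(0, as.numeric(mon + 6L - pmax(absent_until, mon)) + 1)) / 7
    tw <- train_h[, w][team_of]

    if (in_season[w]) {
      play <- frac == 1 & runif(n_p) < p_play
      if (any(play)) {
        u <- runif(sum(play))
        mins <- integer(sum(play))
        full <- u < cf$minutes_full
        bench <- !full & u < cf$minutes_full + cf$minutes_bench
        mins[full] <- 80L
        nb <- sum(bench)
        if (nb) mins[bench] <- 20L + as.integer(floor(runif(nb) * 60))
        nc <- sum(!full & !bench)
        if (nc) mins[!full & !bench] <- 1L + as.integer(floor(runif(nc) * 19))
        M[play, w] <- mins
        P20[play, w] <- mins >= 20L
      }
    }

    # rolling covariates from strictly earlier weeks
    lo12 <- max(1L, w - 52L)
    cnt12 <- if (w > 1L) {
      rowSums(P20[, lo12:(w - 1L), drop = FALSE])
    } else numeric(n_p)
    lo1 <- max(1L, w - 4L)
    fge1 <- if (w > 1L) {
      rowSums(M[, lo1:(w - 1L), drop = FALSE]) / 80
    } else numeric(n_p)
    qk <- findInterval(cnt12, cf$quartile_breaks) + 1L   # 1..4

    u12 <- cnt12 - 19
    eta <- beta_age * (age0 + (w - 1) / 52.18 - cf$age_mean) +
      beta_h * (height - cf$height_mean) + beta_m * (mass - cf$mass_mean) +
      beta_pos * forward + beta_prev * prev_cnt +
      cc[1] * u12 + cc[2] * u12^2 + cc[3] * u12^3 +
      beta_1m_q[qk] * fge1 + b_team[team_of] + b_player

    # the week's exposure decomposes into a training piece and the match
    # piece; drawing the two sequentially is exact for an exponential event
    # process with the match placed at the week's end, and keeps the injury
    # draw consistent with the involvements actually recorded (a player
    # injured in training before the fixture never plays it)
    h1 <- frac * tw
    h2 <- M[, w] / 60
    lam <- cf$baseline_hazard * exp(eta)
    hit_train <- runif(n_p) < -expm1(-lam * h1) & h1 > 0
    hit_match <- !hit_train & runif(n_p) < -expm1(-lam * h2) & h2 > 0
    hit <- which(hit_train | hit_match)
    risk_hours <- risk_hours + h1 + ifelse(hit_train, 0, h2)
    if (detail) {
      panel$fge1[, w] <- fge1; panel$cnt12[, w] <- cnt12
      panel$hours[, w] <- h1 + ifelse(hit_train, 0, h2)
      panel$frac[, w] <- frac; panel$eta[, w] <- eta
    }

    for (i in hit) {
      if (hit_train[i]) {
        at_risk_day <- mon + 0:6 >= absent_until[i]
        early <- which(at_risk_day[1:5])
        dayidx <- if (length(early)) {
          if (length(early) == 1L) early else sample(early, 1L)
        } else {
          late <- which(at_risk_day)
          if (length(late) == 1L) late else sample(late, 1L)
        }
        d <- mon + (dayidx - 1L)
        if (d < mon + 5L && M[i, w] > 0) {
          # injured before the fixture: the involvement never happened
          M[i, w] <- 0
          P20[i, w] <- FALSE
        }
        setting <- "training"
      } else {
        d <- mon + 5L
        setting <- "match"
      }
      dur <- max(cf$absence_min_days,
                 round(rlnorm(1, cf$absence_meanlog, cf$absence_sdlog)))
      inj_p <- c(inj_p, i); inj_d <- c(inj_d, d)
      inj_r <- c(inj_r, d + dur); inj_s <- c(inj_s, setting)
      absent_until[i] <- d + dur
      prev_cnt[i] <- prev_cnt[i] + 1L
    }
  }

  nz <- which(M > 0, arr.ind = TRUE)
  matches <- tibble(
    player_id = player_ids[nz[, 1]],
    team_id = team_ids[team_of[nz[, 1]]],
    match_date = monday[nz[, 2]] + 5L,
    minutes = M[nz]
  )
  matches <- dplyr::arrange(matches, .data$player_id, .data$match_date)

  if (length(inj_p)) {
    injuries <- tibble(
      player_id = player_ids[inj_p], injury_date = inj_d,
      return_date = inj_r, setting = inj_s,
      diagnosis_code = NA_character_
    )
    injuries <- dplyr::arrange(injuries, .data$player_id, .data$injury_date)
  } else {
    warn("simulate_cohort: configuration generated no injuries")
    injuries <- tibble(
      player_id = character(0), injury_date = as.Date(character()),
      return_date = as.Date(character()), setting = character(0),
      diagnosis_code = character(0)
    )
  }

  bundle <- cohort_bundle(players, matches, training, injuries)
  attr(bundle, "truth") <- list(
    config = cf, seed = seed,
    b_team = setNames(b_team, team_ids),
    b_player = setNames(b_player, player_ids),
    beta_per_unit = c(age = beta_age, height = beta_h, mass = beta_m,
                      position_forward = beta_pos, prev_injury = beta_prev,
                      one_month_fge = unname(beta_1m_q[1])),
    beta_1m_by_quartile = beta_1m_q,
    twelve_month_coefs = cc,
    risk_hours = setNames(risk_hours, player_ids)
  )
  if (detail) {
    attr(bundle, "truth")$panel <- c(panel, list(monday = monday))
  }
  bundle
}

#' Tiny hand-auditable fixture cohorts
#'
#' A registry of minimal cohorts whose expected pipeline outputs are known in
#' closed form; used throughout the test-suite oracles.
#'
#' \describe{
#'   \item{two_players_one_injury}{one event whose risk set has exactly two
#'     intervals: the null partial log-likelihood is `-log(2)`.}
#'   \item{tie_break}{two events tied at the same gap duration with a third
#'     interval at risk: Breslow gives `-2 log 3`, Efron `-log 3 - log 2` at
#'     the null.}
#'   \item{zero_exposure_exclusion}{a training-only injury with zero matches
#'     in the preceding 12 months: exactly one interval (one event) is
#'     excluded by [build_intervals()].}
#' }
#'
#' @param name fixture name.
#' @return a `cohort_bundle` with an `expected` attribute describing the
#'   documented outputs.
#' @export
make_fixture <- function(name = c("two_players_one_injury", "tie_break",
                                  "zero_exposure_exclusion")) {
  name <- match.arg(name)
  entry <- as.Date("2020-01-06")   # a Monday
  exit <- as.Date("2020-06-01")
  ply <- function(ids, pos) tibble(
    player_id = ids, team_id = "T1",
    birth_date = as.Date("1994-03-01"), height_cm = 185 + seq_along(ids),
    mass_kg = 100 - seq_along(ids),
    position = rep_len(pos, length(ids)),
    entry_date = entry, exit_date = exit
  )
  mt <- function(id, dates, mins) tibble(
    player_id = id, team_id = "T1", match_date = as.Date(dates),
    minutes = mins
  )
  no_training <- tibble(team_id = character(0),
                        week_start = as.Date(character()),
                        hours = numeric(0))
  inj <- function(id, d, r, s = "match") tibble(
    player_id = id, injury_date = as.Date(d), return_date = as.Date(r),
    setting = s, diagnosis_code = NA_character_
  )

  if (name == "two_players_one_injury") {
    b <- cohort_bundle(
      ply(c("A", "B"), c("forward", "back")),
      dplyr::bind_rows(
        mt("A", "2020-02-01", 80),
        mt("B", c("2020-02-01", "2020-03-14"), c(80, 80))
      ),
      no_training,
      inj("A", "2020-03-01", "2020-03-08")
    )
    attr(b, "expected") <- list(
      n_intervals = 3L, events = c(TRUE, FALSE, FALSE),
      durations = c(80 / 60, 0, 160 / 60),
      null_pll = -log(2)
    )
  } else if (name == "tie_break") {
    b <- cohort_bundle(
      ply(c("C", "D", "E"), c("forward", "back", "forward")),
      dplyr::bind_rows(
        mt("C", "2020-02-01", 80),
        mt("D", "2020-02-01", 80),
        mt("E", c("2020-02-01", "2020-03-07"), c(80, 80))
      ),
      no_training,
      dplyr::bind_rows(
        inj("C", "2020-02-01", "2020-02-15"),
        inj("D", "2020-02-01", "2020-02-15")
      )
    )
    attr(b, "expected") <- list(
      tied_duration = 80 / 60,
      null_pll_breslow = -2 * log(3),
      null_pll_efron = -log(3) - log(2)
    )
  } else {
    training <- tibble(
      team_id = "T1",
      week_start = seq(entry, as.Date("2020-05-25"), by = 7),
      hours = 10
    )
    b <- cohort_bundle(
      ply(c("F", "G"), c("back", "forward")),
      dplyr::bind_rows(
        mt("F", "2020-04-04", 80),
        mt("G", "2020-02-01", 80)
      ),
      training,
      inj("F", "2020-03-01", "2020-03-10", s = "training")
    )
    attr(b, "expected") <- list(
      n_excluded = 1L, n_excluded_events = 1L, n_intervals_kept = 2L
    )
  }
  b
}
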