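#' Rolling match-exposure covariates
#'
#' Workload covariates evaluated at an arbitrary date, using half-open
#' windows `(eval_date - span, eval_date]` so that exposure accrued earlier on
#' the evaluation day itself (typically an injury day) counts:
#' \describe{
#'   \item{12-month match exposure}{`twelve_month_exposure(mode = "count")`:
#'     the number of involvements of at least 20 minutes (inclusive) in the
#'     preceding 365 days — the accumulated/chronic load. A meaningful
#'     substitute appearance of exactly 20 minutes counts.}
#'   \item{12-month FGE}{`mode = "fge"`: total minutes over the same window
#'     divided by 80 (one full-game equivalent), with no minimum-minutes
#'     filter; used in supplementary analyses.}
#'   \item{1-month match exposure}{[one_month_fge()]: full-game equivalents
#'     over the preceding 30 days — the recent/acute load.}
#' }
#'
#' @param matches tibble of match involvements (`player_id`, `match_date`,
#'   `minutes`).
#' @param player_id player to evaluate.
#' @param eval_date evaluation date (the upper, inclusive window bound).
#' @param mode `"count"` (involvements of >= 20 min) or `"fge"`
#'   (sum of minutes / 80).
#' @param players optional roster tibble; when supplied, an unknown
#'   `player_id` is an error rather than an implicit zero.
#' @return a single non-negative number.
#' @examples
#' m <- tibble::tibble(player_id = "p1",
#'                     match_date = as.Date("2020-01-04") + c(0, 7, 14),
#'                     minutes = c(19, 20, 80))
#' twelve_month_exposure(m, "p1", as.Date("2020-02-01"))         # 2 (>=20 only)
#' twelve_month_exposure(m, "p1", as.Date("2020-02-01"), "fge")  # 119/80
#' one_month_fge(m, "p1", as.Date("2020-02-01"))                 # 119/80
#' @seealso [exposure_snapshots()] for batch evaluation,
#'   [quartile_breakpoints()] for chronic-load quartiles.
#' @export
twelve_month_exposure <- function(matches, player_id, eval_date,
                                  mode = c("count", "fge"), players = NULL) {
  mode <- match.arg(mode)
  assert_date_scalar(eval_date, "eval_date")
  check_known_player(player_id, matches, players)
  mm <- matches[matches$player_id == player_id &
                  matches$match_date > eval_date - 365 &
                  matches$match_date <= eval_date, , drop = FALSE]
  if (mode == "count") {
    sum(mm$minutes >= 20)
  } else {
    sum(mm$minutes) / 80
  }
}

#' @rdname twelve_month_exposure
#' @export
one_month_fge <- function(matches, player_id, eval_date, players = NULL) {
  assert_date_scalar(eval_date, "eval_date")
  check_known_player(player_id, matches, players)
  mm <- matches[matches$player_id == player_id &
                  matches$match_date > eval_date - 30 &
                  matches$match_date <= eval_date, , drop = FALSE]
  sum(mm$minutes) / 80
}

check_known_player <- function(player_id, matches, players) {
  if (length(player_id) != 1L || is.na(player_id)) {
    stop_validation("`player_id` must be a single id")
  }
  if (!is.null(players) && !player_id %in% players$player_id) {
    stop_referential(sprintf("unknown player_id: %s", player_id))
  }
  invisible(TRUE)
}

#' Batch exposure snapshots
#'
#' Evaluates the three rolling workload covariates for many (player, date)
#' pairs at once; the result mirrors the optional `exposures.csv` output.
#'
#' @param matches match involvements tibble.
#' @param at tibble with columns `player_id` and `eval_date`.
#' @return `at` with columns `twelve_month_matches`, `twelve_month_fge` and
#'   `one_month_fge` appended.
#' @export
exposure_snapshots <- function(matches, at) {
  stopifnot(all(c("player_id", "eval_date") %in% names(at)))
  by_player <- split(matches[c("match_date", "minutes")], matches$player_id)
  out <- purrr::pmap(list(at$player_id, as.list(at$eval_date)),
    function(pid, d) {
      mm <- by_player[[pid]]
      if (is.null(mm)) {
        return(c(0, 0, 0))
      }
      in12 <- mm$match_date > d - 365 & mm$match_date <= d
      in1 <- mm$match_date > d - 30 & mm$match_date <= d
      c(sum(in12 & mm$minutes >= 20), sum(mm$minutes[in12]) / 80,
        sum(mm$minutes[in1]) / 80)
    })
  out <- do.call(rbind, out)
  dplyr::bind_cols(at, tibble(
    twelve_month_matches = as.integer(out[, 1]),
    twelve_month_fge = out[, 2], one_month_fge = out[, 3]
  ))
}

#' Chronic-load quartile breakpoints
#'
#' Computes the 25th/50th/75th percentiles of a set of 12-month match-exposure
#' values (linear interpolation between order statistics, the common default
#' quantile rule), defining bins `Q1 = [min, b1)`, `Q2 = [b1, b2)`,
#' `Q3 = [b2, b3)`, `Q4 = [b3, max]`. Cohort-derived breakpoints can be
#' overridden with fixed user-supplied ones, e.g. `c(12, 22, 29)` reproduces
#' integer-count bins `<12`, `12–21`, `22–28`, `>28`.
#'
#' @param values numeric vector of 12-month match counts.
#' @param breaks optional length-3 increasing numeric vector of fixed
#'   breakpoints overriding the computed percentiles.
#' @return numeric length-3 vector of breakpoints.
#' @examples
#' quartile_breakpoints(1:40)               # 10.75 20.50 30.25
#' assign_quartile(c(5, 12, 25, 30), breaks = c(12, 22, 29))
#' @export
quartile_breakpoints <- function(values, breaks = NULL) {
  if (!is.null(breaks)) {
    if (length(breaks) != 3L || is.unsorted(breaks, strictly = TRUE)) {
      stop_validation("`breaks` must be three strictly increasing numbers")
    }
    return(as.numeric(breaks))
  }
  values <- values[!is.na(values)]
  if (length(values) < 4L) {
    stop_validation("need at least 4 observations to form quartiles")
  }
  bp <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  if (is.unsorted(bp, strictly = TRUE)) {
    stop_validation("degenerate quartiles: breakpoints are not distinct")
  }
  bp
}

#' @rdname quartile_breakpoints
#' @param x numeric vector to bin.
#' @export
assign_quartile <- function(x, breaks) {
  breaks <- quartile_breakpoints(x, breaks = breaks)
  cut(x, c(-Inf, breaks, Inf), labels = paste0("Q", 1:4), right = FALSE)
}

#' Exposure hours over an interval
#'
#' Total at-risk exposure accrued by one player over the half-open calendar
#' interval `(from_date, to_date]`: individual match minutes divided by 60,
#' plus the player's team's weekly group training hours pro-rated by the
#' number of overlapping days out of 7. This is the survival time axis of the
#' gap-time model (exposure since return from the previous injury).
#'
#' @param matches match involvements tibble.
#' @param training weekly team training tibble (`team_id`, `week_start`,
#'   `hours`).
#' @param player_id player to evaluate.
#' @param from_date,to_date interval bounds, `from_date <= to_date`.
#' @param team_id the team whose group training the player attended over the
#'   interval.
#' @return non-negative hours.
#' @examples
#' m <- tibble::tibble(player_id = "p1", match_date = as.Date("2020-01-11"),
#'                     minutes = 80)
#' tr <- tibble::tibble(team_id = "t1", week_start = as.Date("2020-01-06"),
#'                      hours = 10)
#' exposure_hours(m, tr, "p1", as.Date("2020-01-05"), as.Date("2020-01-12"),
#'                team_id = "t1")  # 80/60 + 10
#' @export
exposure_hours <- function(matches, training, player_id, from_date, to_date,
                           team_id) {
  assert_date_scalar(from_date, "from_date")
  assert_date_scalar(to_date, "to_date")
  if (from_date > to_date) {
    stop_validation("`from_date` must not be after `to_date`")
  }
  if (from_date == to_date) {
    return(0)
  }
  mm <- matches[matches$player_id == player_id &
                  matches$match_date > from_date &
                  matches$match_date <= to_date, , drop = FALSE]
  match_h <- sum(mm$minutes) / 60
  tw <- training[training$team_id %in% team_id, , drop = FALSE]
  if (nrow(tw)) {
    # day d is covered when from_date < d <= to_date; week covers
    # [week_start, week_start + 6]
    lo <- pmax(as.numeric(tw$week_start), as.numeric(from_date) + 1)
    hi <- pmin(as.numeric(tw$week_start) + 6, as.numeric(to_date))
    overlap <- pmax(0, hi - lo + 1)
    train_h <- sum(tw$hours * overlap / 7)
  } else {
    train_h <- 0
  }
  match_h + train_h
}

#' Injury incidence rates per 1000 exposure hours
#'
#' Definitional surveillance rates: `injuries / hours * 1000`, computed per
#' season and per setting (match vs training), summarised as mean and SD
#' across seasons per setting.
#'
#' @param injuries tibble with columns `season` and `setting`, one row per
#'   injury.
#' @param exposure tibble with columns `season`, `setting` and `hours`
#'   (total player-hours at risk in that cell).
#' @return per-season tibble (`setting`, `season`, `injuries`, `hours`,
#'   `rate`) with a `summary` attribute holding the across-season mean and SD
#'   per setting (retrieve with `attr(x, "summary")`).
#' @examples
#' inj <- tibble::tibble(season = rep(1, 50), setting = "match")
#' exp <- tibble::tibble(season = 1, setting = "match", hours = 582)
#' incidence_rates(inj, exp)  # 85.9 per 1000 h
#' @export
incidence_rates <- function(injuries, exposure) {
  stopifnot(all(c("season", "setting") %in% names(injuries)),
            all(c("season", "setting", "hours") %in% names(exposure)))
  counts <- dplyr::count(injuries, .data$setting, .data$season,
                         name = "injuries")
  out <- dplyr::left_join(exposure, counts, by = c("setting", "season"))
  out$injuries[is.na(out$injuries)] <- 0L
  if (any(out$hours <= 0 & out$injuries > 0)) {
    stop_validation("undefined incidence rate: injuries recorded in a cell with zero exposure hours")
  }
  if (any(out$hours <= 0)) {
    stop_validation("undefined incidence rate: zero exposure hours")
  }
  out$rate <- out$injuries / out$hours * 1000
  out <- dplyr::arrange(out[c("setting", "season", "injuries", "hours", "rate")],
                        .data$setting, .data$season)
  summ <- dplyr::summarise(
    dplyr::group_by(out, .data$setting),
    mean_rate = mean(.data$rate),
    sd_rate = if (dplyr::n() > 1) sd(.data$rate) else NA_real_,
    n_seasons = dplyr::n(), .groups = "drop"
  )
  attr(out, "summary") <- summ
  out
}
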