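#' Build recurrent-event gap-time risk intervals
#'
#' Converts a validated cohort into the data the hazard model consumes. For
#' each player (and each roster span, if the player transferred clubs) the
#' survival clock restarts at study entry and at every return from injury:
#' interval 1 runs from entry to the first injury (an event) or to exit
#' (censored); interval k runs from the previous return date to injury k or
#' exit. Injury-absence spells contribute no risk time. The survival axis is
#' cumulative exposure hours within the interval (match minutes / 60 plus
#' pro-rated team training hours) — gap time in exposure hours — and each
#' record carries the covariates age (years), height, mass, position,
#' `prev_injury_count` (injuries of that player earlier in the dataset),
#' `twelve_month_matches`, `twelve_month_fge` and `one_month_fge`.
#'
#' `covariate_update` controls how the rolling workload covariates enter:
#' \describe{
#'   \item{`"weekly"` (default)}{counting-process form: every gap interval is
#'     split at calendar week boundaries into segments
#'     `(gap_start_hours, gap_stop_hours]` on the exposure-hour gap axis
#'     (delayed entry), each carrying the covariate values in force at the
#'     segment's start date. This is the standard treatment of time-varying
#'     covariates: at every event time the risk set sees each player's
#'     current workload.}
#'   \item{`"interval_end"`}{one record per gap interval with all covariates
#'     frozen at their end-date values (the injury or censoring date). A
#'     simpler surface, but for rapidly varying covariates such as 30-day
#'     load the endpoint value misrepresents the at-risk person-time and
#'     attenuates effect estimates; retained for comparison.}
#' }
#'
#' Risk records whose 12-month match exposure is zero are excluded (players
#' out of match play for a year are not part of the at-risk population); the
#' number dropped is recorded in the `n_excluded_zero_exposure` attribute
#' and reported as a message. Event records with no accrued exposure (injury
#' on the return day) are retained with the duration floored at
#' `zero_duration_floor` hours so that the event stays in the risk set:
#' dropping events would bias rates downward.
#'
#' With `time_axis = "calendar_days"` (only with
#' `covariate_update = "interval_end"`) the duration becomes calendar days
#' and the exposure hours are kept in `log_exposure_offset` for use as a
#' linear-predictor offset — the alternative reading of exposure adjustment.
#'
#' @param cohort a `cohort_bundle`.
#' @param censor_date optional administrative censoring date applied on top
#'   of per-player exit dates.
#' @param covariate_update `"weekly"` (counting-process segments) or
#'   `"interval_end"` (one record per interval).
#' @param drop_zero_exposure drop records with zero 12-month match exposure
#'   (default `TRUE`, the headline analysis rule).
#' @param time_axis `"exposure_hours"` (default) or `"calendar_days"`.
#' @param zero_duration_floor floor, in hours, for zero-exposure event
#'   records.
#' @param quiet suppress the exclusion message.
#' @return tibble of risk records ordered by player and time, with
#'   attributes `n_excluded_zero_exposure` and `n_excluded_events`.
#' @examples
#' b <- make_fixture("two_players_one_injury")
#' build_intervals(b, covariate_update = "interval_end")
#' @export
build_intervals <- function(cohort, censor_date = NULL,
                            covariate_update = c("weekly", "interval_end"),
                            drop_zero_exposure = TRUE,
                            time_axis = c("exposure_hours", "calendar_days"),
                            zero_duration_floor = 0.01, quiet = FALSE) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  covariate_update <- match.arg(covariate_update)
  time_axis <- match.arg(time_axis)
  if (time_axis == "calendar_days" && covariate_update != "interval_end") {
    stop_validation("time_axis = 'calendar_days' requires covariate_update = 'interval_end'")
  }
  base <- interval_skeleton(cohort, censor_date)
  if (covariate_update == "interval_end") {
    iv <- endpoint_covariates(cohort, base)
  } else {
    iv <- weekly_segments(cohort, base)
  }

  n_excl <- 0L
  n_excl_ev <- 0L
  if (drop_zero_exposure) {
    drop <- iv$twelve_month_matches == 0L
    n_excl <- sum(drop)
    n_excl_ev <- sum(drop & iv$event)
    if (n_excl && !quiet) {
      inform(sprintf(
        "build_intervals: excluded %d record(s) (%d event(s)) with zero 12-month match exposure",
        n_excl, n_excl_ev
      ))
    }
    iv <- iv[!drop, , drop = FALSE]
  }
  if (covariate_update == "interval_end") {
    iv$duration_hours[iv$event & iv$duration_hours <= 0] <- zero_duration_floor
    if (time_axis == "calendar_days") {
      iv$log_exposure_offset <- log(pmax(iv$duration_hours, zero_duration_floor))
      iv$duration_hours <- as.numeric(iv$end_date - iv$start_date)
      iv$duration_hours[iv$event & iv$duration_hours <= 0] <- 0.5
    }
  } else {
    z <- iv$event & iv$gap_stop_hours <= iv$gap_start_hours
    iv$gap_stop_hours[z] <- iv$gap_start_hours[z] + zero_duration_floor
    iv$duration_hours[z] <- zero_duration_floor
  }

  iv <- dplyr::arrange(iv, .data$player_id, .data$start_date)
  attr(iv, "n_excluded_zero_exposure") <- n_excl
  attr(iv, "n_excluded_events") <- n_excl_ev
  attr(iv, "time_axis") <- time_axis
  attr(iv, "covariate_update") <- covariate_update
  iv
}

# one row per gap interval: bounds, event flag, constant covariates
interval_skeleton <- function(cohort, censor_date) {
  p <- cohort$players
  inj_by_player <- split(cohort$injuries, cohort$injuries$player_id)
  rows <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    pid <- p$player_id[i]
    entry <- p$entry_date[i]
    exit <- p$exit_date[i]
    if (!is.null(censor_date)) exit <- min(exit, censor_date)
    if (exit < entry) next
    inj <- inj_by_player[[pid]]
    n_before_span <- 0L
    if (!is.null(inj)) {
      inj <- inj[order(inj$injury_date), , drop = FALSE]
      n_before_span <- sum(inj$injury_date < entry)
      inj <- inj[inj$injury_date >= entry & inj$injury_date <= exit, ,
                 drop = FALSE]
    }
    starts <- entry
    ends <- as.Date(character())
    events <- logical()
    if (!is.null(inj) && nrow(inj)) {
      for (k in seq_len(nrow(inj))) {
        ends <- c(ends, inj$injury_date[k])
        events <- c(events, TRUE)
        nxt <- inj$return_date[k]
        if (nxt <= exit) starts <- c(starts, nxt)
      }
    }
    if (length(starts) > length(ends)) {
      ends <- c(ends, exit)
      events <- c(events, FALSE)
    }
    k <- seq_along(ends)
    rows[[i]] <- tibble(
      player_id = pid, team_id = p$team_id[i],
      start_date = starts[k], end_date = ends,
      event = events,
      prev_injury_count = n_before_span + cumsum(events) -
        ifelse(events, 1L, 0L),
      birth_date = p$birth_date[i], height_cm = p$height_cm[i],
      mass_kg = p$mass_kg[i], position = p$position[i]
    )
  }
  iv <- dplyr::bind_rows(rows)
  if (!nrow(iv)) stop_validation("cohort produced no risk intervals")
  iv$interval_id <- seq_len(nrow(iv))
  iv
}

endpoint_covariates <- function(cohort, iv) {
  match_by_player <- split(cohort$matches, cohort$matches$player_id)
  train_by_team <- split(cohort$training, cohort$training$team_id)
  iv$age_years <- as.numeric(iv$end_date - iv$birth_date) / 365.25
  iv$birth_date <- NULL
  snaps <- exposure_snapshots(
    cohort$matches,
    tibble(player_id = iv$player_id, eval_date = iv$end_date)
  )
  iv$twelve_month_matches <- snaps$twelve_month_matches
  iv$twelve_month_fge <- snaps$twelve_month_fge
  iv$one_month_fge <- snaps$one_month_fge
  iv$duration_hours <- vapply(seq_len(nrow(iv)), function(j) {
    exposure_hours(
      match_by_player[[iv$player_id[j]]] %||%
        cohort$matches[0, , drop = FALSE],
      train_by_team[[iv$team_id[j]]] %||%
        cohort$training[0, , drop = FALSE],
      iv$player_id[j], iv$start_date[j], iv$end_date[j], iv$team_id[j]
    )
  }, numeric(1))
  iv[c("player_id", "team_id", "interval_id", "start_date", "end_date",
       "event", "duration_hours", "age_years", "height_cm", "mass_kg",
       "position", "prev_injury_count", "twelve_month_matches",
       "twelve_month_fge", "one_month_fge")]
}

# split gap intervals at week boundaries (Sundays) into counting-process
# segments; covariates are evaluated at each segment's start date, so each
# risk segment carries the workload in force while it was at risk
weekly_segments <- function(cohort, iv) {
  match_by_player <- split(cohort$matches, cohort$matches$player_id)
  train_by_team <- split(cohort$training, cohort$training$team_id)
  out <- vector("list", nrow(iv))
  oi <- 0L
  for (pid in unique(iv$player_id)) {
    pv <- iv[iv$player_id == pid, , drop = FALSE]
    mm <- match_by_player[[pid]]
    md <- if (is.null(mm)) as.Date(character()) else mm$match_date
    mo <- order(md)
    md <- md[mo]
    mins <- if (is.null(mm)) numeric(0) else mm$minutes[mo]
    cmin <- c(0, cumsum(mins))
    cmin20 <- c(0, cumsum(mins >= 20))
    md_n <- as.numeric(md)

    for (j in seq_len(nrow(pv))) {
      s <- pv$start_date[j]
      e <- pv$end_date[j]
      tr <- train_by_team[[pv$team_id[j]]]
      if (e <= s) {
        bnd <- c(s, e)
      } else {
        wd <- as.POSIXlt(s)$wday               # Sunday = 0
        first_sun <- s + ifelse(wd == 0L, 7L, 7L - wd)
        suns <- if (first_sun < e) seq(first_sun, e - 1, by = 7) else
          as.Date(character())
        bnd <- c(s, suns, e)
      }
      K <- length(bnd) - 1L
      b0 <- bnd[-length(bnd)]
      b1 <- bnd[-1]
      ndays <- as.numeric(b1 - b0)

      # match minutes per segment: matches in (b0, b1]
      hi <- findInterval(as.numeric(b1), md_n)
      lo <- findInterval(as.numeric(b0), md_n)
      match_h <- (cmin[hi + 1L] - cmin[lo + 1L]) / 60

      # training hours: each segment lies inside one Monday-Sunday week
      train_week_h <- numeric(K)
      if (!is.null(tr) && nrow(tr)) {
        wmon <- b1 - (as.POSIXlt(b1)$wday + 6L) %% 7L
        ix <- match(as.numeric(wmon), as.numeric(tr$week_start))
        train_week_h <- ifelse(is.na(ix), 0, tr$hours[ix])
      }
      train_h <- train_week_h * ndays / 7

      h <- match_h + train_h
      cum <- cumsum(h)
      gap_start <- c(0, cum[-K])
      gap_stop <- cum
      ev <- c(rep(FALSE, K - 1L), pv$event[j])

      # rolling covariates in force over the segment: evaluated at its first
      # calendar day (b0 + 1), i.e. the workload accrued before the
      # segment's person-time began
      d_n <- as.numeric(b0) + 1
      cnt12 <- (cmin20[findInterval(d_n, md_n) + 1L] -
                  cmin20[findInterval(d_n - 365, md_n) + 1L])
      fge12 <- (cmin[findInterval(d_n, md_n) + 1L] -
                  cmin[findInterval(d_n - 365, md_n) + 1L]) / 80
      fge1 <- (cmin[findInterval(d_n, md_n) + 1L] -
                 cmin[findInterval(d_n - 30, md_n) + 1L]) / 80

      keep <- which(h > 0 | ev)
      if (!length(keep)) next
      nk <- length(keep)
      oi <- oi + 1L
      out[[oi]] <- list(
        player_id = rep(pid, nk), team_id = rep(pv$team_id[j], nk),
        interval_id = rep(pv$interval_id[j], nk),
        start_date = as.numeric(b0[keep]), end_date = as.numeric(b1[keep]),
        event = ev[keep],
        gap_start_hours = gap_start[keep], gap_stop_hours = gap_stop[keep],
        duration_hours = h[keep],
        # age is treated as fixed within a gap interval (drift < 0.1 y);
        # keeping it constant lets identical-covariate segments merge
        age_years = rep(as.numeric(s - pv$birth_date[j]) / 365.25, nk),
        height_cm = rep(pv$height_cm[j], nk), mass_kg = rep(pv$mass_kg[j], nk),
        position = rep(pv$position[j], nk),
        prev_injury_count = rep(pv$prev_injury_count[j], nk),
        twelve_month_matches = as.integer(cnt12[keep]),
        twelve_month_fge = fge12[keep], one_month_fge = fge1[keep]
      )
    }
  }
  out <- out[seq_len(oi)]
  cols <- names(out[[1L]])
  res <- lapply(setNames(cols, cols), function(cn) {
    do.call(c, lapply(out, `[[`, cn))
  })
  res$start_date <- as.Date(res$start_date, origin = "1970-01-01")
  res$end_date <- as.Date(res$end_date, origin = "1970-01-01")
  tibble::new_tibble(res, nrow = length(res[[1L]]))
}

#' Two-standard-deviation covariate scaling
#'
#' Rescales continuous covariates to `(x - mean) / (2 * SD)` so that a unit
#' change on the transformed scale corresponds to a 2-SD change on the
#' original scale; hazard ratios for such covariates are then directly
#' comparable across predictors. The means and SDs are retained in the
#' `scale_report` attribute for back-transformation (`two_sd` is the original
#' units spanned by one transformed unit).
#'
#' @param data a data frame (typically risk intervals).
#' @param vars character vector of column names to rescale.
#' @return `data` with the named columns transformed in place; retrieve the
#'   scale report with [scale_report()].
#' @examples
#' iv <- tibble::tibble(x = c(1, 2, 3, 4))
#' scale_report(standardize_2sd(iv, "x"))
#' @export
standardize_2sd <- function(data, vars) {
  miss <- setdiff(vars, names(data))
  if (length(miss)) {
    stop_validation(sprintf("standardize_2sd: no such column(s): %s",
                            paste(miss, collapse = ", ")))
  }
  rep <- vector("list", length(vars))
  for (i in seq_along(vars)) {
    v <- vars[i]
    x <- data[[v]]
    if (!is.numeric(x)) {
      stop_validation(sprintf("standardize_2sd: column '%s' is not numeric", v))
    }
    m <- mean(x)
    s <- sd(x)
    if (!is.finite(s) || s <= 0) {
      stop_validation(sprintf("standardize_2sd: column '%s' has zero SD", v))
    }
    data[[v]] <- (x - m) / (2 * s)
    rep[[i]] <- tibble(variable = v, mean = m, sd = s, two_sd = 2 * s)
  }
  attr(data, "scale_report") <- dplyr::bind_rows(
    attr(data, "scale_report"), dplyr::bind_rows(rep)
  )
  data
}

#' @rdname standardize_2sd
#' @export
scale_report <- function(data) {
  attr(data, "scale_report")
}
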