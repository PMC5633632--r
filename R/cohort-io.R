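#' Cohort table exchange
#'
#' A cohort bundle is a named list of four tibbles describing a multi-team
#' longitudinal squad: `players` (roster and anthropometrics), `matches`
#' (per-player match involvements in minutes), `training` (weekly team-level
#' group training hours) and `injuries` (time-loss injury spells).
#' [read_cohort()] is the single entry point for file input: it parses the
#' four CSV files, checks every type invariant and all cross-references, and
#' fails with a typed condition (`matchrisk_schema_error`,
#' `matchrisk_referential_error` or `matchrisk_validation_error`) rather than
#' silently coercing. [write_cohort()] is its exact inverse: writing a valid
#' bundle and reading it back reproduces the bundle to full precision.
#'
#' File dialect: comma-separated UTF-8 with a mandatory header row and
#' ISO-8601 dates. Expected columns are
#' \describe{
#'   \item{players.csv}{player_id, team_id, birth_date, height_cm, mass_kg,
#'     position (`forward`/`back`), entry_date, exit_date}
#'   \item{matches.csv}{player_id, team_id, match_date, minutes}
#'   \item{training.csv}{team_id, week_start (a Monday), hours}
#'   \item{injuries.csv}{player_id, injury_date, return_date, setting
#'     (`match`/`training`), diagnosis_code (optional free text)}
#' }
#'
#' A player who transfers between clubs appears as several roster rows with
#' non-overlapping participation spans; exposure histories follow the player
#' across teams because rolling workload windows are properties of the player,
#' not the club. Missing anthropometrics or dates are a hard error: the
#' downstream hazard model adjusts for all covariates and performs no
#' imputation. A time-loss injury must cost more than 24 h, so
#' `return_date > injury_date` is enforced.
#'
#' @param path directory containing the four CSV files.
#' @param files named character vector overriding the default file names.
#' @param bundle a cohort bundle as returned by [read_cohort()],
#'   [cohort_bundle()] or [simulate_cohort()].
#' @param players,matches,training,injuries in-memory tibbles with the
#'   columns listed above.
#' @return [read_cohort()] and [cohort_bundle()] return a validated
#'   `cohort_bundle`; [write_cohort()] invisibly returns the file paths it
#'   wrote; [validate_cohort()] invisibly returns its input.
#' @examples
#' b <- make_fixture("two_players_one_injury")
#' dir <- file.path(tempdir(), "cohort-demo")
#' write_cohort(b, dir)
#' b2 <- read_cohort(dir)
#' identical(b$players$player_id, b2$players$player_id)
#' @name cohort_io
NULL

cohort_file_names <- c(
  players = "players.csv", matches = "matches.csv",
  training = "training.csv", injuries = "injuries.csv"
)

cohort_col_types <- list(
  players = readr::cols(
    player_id = readr::col_character(), team_id = readr::col_character(),
    birth_date = readr::col_date(), height_cm = readr::col_double(),
    mass_kg = readr::col_double(), position = readr::col_character(),
    entry_date = readr::col_date(), exit_date = readr::col_date()
  ),
  matches = readr::cols(
    player_id = readr::col_character(), team_id = readr::col_character(),
    match_date = readr::col_date(), minutes = readr::col_double()
  ),
  training = readr::cols(
    team_id = readr::col_character(), week_start = readr::col_date(),
    hours = readr::col_double()
  ),
  injuries = readr::cols(
    player_id = readr::col_character(), injury_date = readr::col_date(),
    return_date = readr::col_date(), setting = readr::col_character(),
    diagnosis_code = readr::col_character()
  )
)

#' @rdname cohort_io
#' @export
read_cohort <- function(path, files = cohort_file_names) {
  files <- utils::modifyList(as.list(cohort_file_names), as.list(files))
  tabs <- lapply(names(cohort_file_names), function(tab) {
    f <- file.path(path, files[[tab]])
    if (!file.exists(f)) {
      stop_schema(sprintf("cohort file not found: %s", f))
    }
    spec <- cohort_col_types[[tab]]
    hdr <- names(spec$cols)
    got <- names(readr::read_csv(f, n_max = 0, col_types = readr::cols(),
                                 show_col_types = FALSE))
    missing <- setdiff(hdr, got)
    if (length(missing)) {
      stop_schema(sprintf(
        "%s: missing required column%s: %s",
        files[[tab]], if (length(missing) > 1) "s" else "",
        paste(missing, collapse = ", ")
      ))
    }
    out <- readr::read_csv(f, col_types = spec, show_col_types = FALSE,
                           progress = FALSE)
    prob <- readr::problems(out)
    if (nrow(prob)) {
      stop_schema(sprintf(
        "%s: %d parsing problem(s), first at row %d column %d (expected %s)",
        files[[tab]], nrow(prob), prob$row[1], prob$col[1], prob$expected[1]
      ))
    }
    out[hdr]
  })
  names(tabs) <- names(cohort_file_names)
  cohort_bundle(tabs$players, tabs$matches, tabs$training, tabs$injuries)
}

#' @rdname cohort_io
#' @export
write_cohort <- function(bundle, path, files = cohort_file_names) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  files <- utils::modifyList(as.list(cohort_file_names), as.list(files))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  out <- vapply(names(cohort_file_names), function(tab) {
    f <- file.path(path, files[[tab]])
    readr::write_csv(bundle[[tab]], f, progress = FALSE)
    f
  }, character(1))
  invisible(out)
}

#' @rdname cohort_io
#' @export
cohort_bundle <- function(players, matches, training, injuries) {
  b <- list(
    players = as_tibble(players), matches = as_tibble(matches),
    training = as_tibble(training), injuries = as_tibble(injuries)
  )
  validate_cohort(b)
  structure(b, class = c("cohort_bundle", "list"))
}

#' @rdname cohort_io
#' @export
validate_cohort <- function(bundle) {
  p <- bundle$players; m <- bundle$matches
  tr <- bundle$training; inj <- bundle$injuries

  for (tab in names(cohort_col_types)) {
    need <- names(cohort_col_types[[tab]]$cols)
    got <- names(bundle[[tab]])
    missing <- setdiff(need, got)
    if (length(missing)) {
      stop_schema(sprintf("%s table: missing column(s): %s", tab,
                          paste(missing, collapse = ", ")))
    }
  }

  # completeness: no imputation downstream, so required fields are hard errors
  req <- list(
    players = setdiff(names(p), character()),
    matches = names(m), training = names(tr),
    injuries = setdiff(names(inj), "diagnosis_code")
  )
  for (tab in names(req)) {
    d <- bundle[[tab]][req[[tab]]]
    bad <- which(!complete.cases(d))
    if (length(bad)) {
      stop_validation(sprintf("%s table: missing values in row(s) %s", tab,
                              paste(head(bad, 5), collapse = ", ")))
    }
  }

  if (anyDuplicated(p[c("player_id", "entry_date")])) {
    stop_validation("players table: duplicated (player_id, entry_date) rows")
  }
  if (!all(p$position %in% c("forward", "back"))) {
    stop_validation("players table: position must be 'forward' or 'back'")
  }
  if (!all(p$height_cm > 120 & p$height_cm < 230)) {
    stop_validation("players table: height_cm outside (120, 230)")
  }
  if (!all(p$mass_kg > 50 & p$mass_kg < 180)) {
    stop_validation("players table: mass_kg outside (50, 180)")
  }
  if (!all(p$exit_date >= p$entry_date)) {
    stop_validation("players table: exit_date earlier than entry_date")
  }
  # transfer spans of one player must not overlap
  sp <- p[order(p$player_id, p$entry_date), ]
  same <- duplicated(sp$player_id)
  if (any(same & sp$entry_date <= c(as.Date(NA), head(sp$exit_date, -1)))) {
    stop_validation("players table: overlapping roster spans for one player")
  }

  if (!all(m$minutes >= 0 & m$minutes <= 100)) {
    stop_validation("matches table: minutes outside [0, 100]")
  }
  orphan <- setdiff(m$player_id, p$player_id)
  if (length(orphan)) {
    stop_referential(sprintf("matches table: unknown player_id: %s",
                             paste(head(orphan, 5), collapse = ", ")))
  }
  # each involvement must fall inside one of the player's roster spans
  spans <- p[c("player_id", "entry_date", "exit_date")]
  mm <- dplyr::left_join(
    dplyr::mutate(m, ..row = dplyr::row_number()), spans,
    by = "player_id", relationship = "many-to-many"
  )
  ok <- dplyr::summarise(
    dplyr::group_by(mm, .data$..row),
    ok = any(.data$match_date >= .data$entry_date &
               .data$match_date <= .data$exit_date),
    .groups = "drop"
  )
  if (!all(ok$ok)) {
    stop_validation(sprintf(
      "matches table: involvement outside the player's participation span, row(s) %s",
      paste(head(ok$..row[!ok$ok], 5), collapse = ", ")
    ))
  }

  if (!all(tr$hours >= 0)) {
    stop_validation("training table: negative hours")
  }
  if (anyDuplicated(tr[c("team_id", "week_start")])) {
    stop_validation("training table: more than one record per (team, week)")
  }
  if (nrow(tr) && !all(as.POSIXlt(tr$week_start)$wday == 1L)) {
    stop_validation("training table: week_start must be a Monday")
  }

  orphan <- setdiff(inj$player_id, p$player_id)
  if (length(orphan)) {
    stop_referential(sprintf("injuries table: unknown player_id: %s",
                             paste(head(orphan, 5), collapse = ", ")))
  }
  if (nrow(inj)) {
    # time loss must exceed 24 h, so the return day is strictly later
    bad <- which(inj$return_date <= inj$injury_date)
    if (length(bad)) {
      stop_validation(sprintf(
        "injuries table: return_date not after injury_date (time loss must exceed 24 h), row(s) %s",
        paste(head(bad, 5), collapse = ", ")
      ))
    }
    si <- inj[order(inj$player_id, inj$injury_date), ]
    same <- duplicated(si$player_id)
    overl <- same & si$injury_date < c(as.Date(NA), head(si$return_date, -1))
    if (any(overl, na.rm = TRUE)) {
      key <- si[which(overl), c("player_id", "injury_date")]
      stop_validation(sprintf(
        "injuries table: overlapping injury spells for player(s) %s",
        paste(head(unique(key$player_id), 5), collapse = ", ")
      ))
    }
    if (!all(inj$setting %in% c("match", "training"))) {
      stop_validation("injuries table: setting must be 'match' or 'training'")
    }
  }
  invisible(bundle)
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle>\n")
  cat(sprintf("  players : %5d rows (%d players, %d teams)\n",
              nrow(x$players), length(unique(x$players$player_id)),
              length(unique(x$players$team_id))))
  cat(sprintf("  matches : %5d involvements\n", nrow(x$matches)))
  cat(sprintf("  training: %5d team-weeks\n", nrow(x$training)))
  cat(sprintf("  injuries: %5d time-loss spells\n", nrow(x$injuries)))
  invisible(x)
}
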