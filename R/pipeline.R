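#' Run the full exposure-to-inference pipeline
#'
#' Orchestrates simulate/load -> exposure covariates -> risk intervals ->
#' frailty fits -> model comparison -> MBI classification -> hazard-ratio
#' curve, writing all tabular outputs as CSV plus a JSON run manifest into
#' `out_dir`. Outputs are staged in a temporary sibling directory and moved
#' into place only on success, so an aborted run never leaves partial
#' results.
#'
#' The configuration is a nested list (or a YAML file with the same
#' structure):
#' \preformatted{
#' cohort:
#'   dir: path/to/cohort        # read four CSVs; or
#'   sim: {n_teams: 12, players_per_team: 45, n_seasons: 3, ...}
#'   seed: 1
#' model:
#'   covariates: [age_years, height_cm, mass_kg, position, prev_injury_count]
#'   twelve_month_degree: 3     # poly_c degree, or "select"
#'   interaction: true          # acute x chronic-quartile interaction model
#'   random: [none, player, team_player]
#'   ties: efron
#' }
#' The first entry of `model$random` tagged `team_player` (else the last
#' entry) is the headline model used for `fit.csv`, the MBI table and the
#' hazard-ratio curve.
#'
#' Files written: `exposures.csv`, `intervals.csv`, `fit.csv`,
#' `comparison.csv`, `mbi.csv`, `hr_curve.csv`, `interaction.csv` (when
#' requested) and `manifest.json` (config hash, seed, package version, input
#' digests, output digests, timestamps).
#'
#' @param config a list as above, or the path of a YAML file holding it.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the fitted models, tables and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort(sprintf("pipeline stage 'config': file not found: %s", config),
            class = c("matchrisk_pipeline_error", "matchrisk_error"))
    }
    config <- yaml::read_yaml(config)
  }
  say <- function(...) if (!quiet) inform(sprintf(...))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", what,
                    conditionMessage(e)),
            class = c("matchrisk_pipeline_error", "matchrisk_error"),
            parent = e)
    })
  }

  cohort_cfg <- config$cohort %||%
    abort("config lacks a 'cohort' section",
          class = c("matchrisk_pipeline_error", "matchrisk_error"))
  input_digests <- character(0)
  cohort <- stage("cohort", {
    if (!is.null(cohort_cfg$dir)) {
      files <- file.path(cohort_cfg$dir, cohort_file_names)
      input_digests <- tools::md5sum(files[file.exists(files)])
      read_cohort(cohort_cfg$dir)
    } else {
      cfg <- do.call(sim_config, as_sim_args(cohort_cfg$sim %||% list()))
      simulate_cohort(cfg, seed = cohort_cfg$seed %||% 1L)
    }
  })
  say("cohort: %d players, %d involvements, %d injuries",
      nrow(cohort$players), nrow(cohort$matches), nrow(cohort$injuries))

  mcfg <- config$model %||% list()
  covs <- mcfg$covariates %||%
    c("age_years", "height_cm", "mass_kg", "position", "prev_injury_count")
  randoms <- mcfg$random %||% c("none", "player", "team_player")
  ties <- mcfg$ties %||% "efron"

  iv <- stage("build", build_intervals(cohort, quiet = quiet))
  n_excluded <- attr(iv, "n_excluded_zero_exposure")
  say("build: %d intervals, %d events, %d excluded (zero 12-month exposure)",
      nrow(iv), sum(iv$event), n_excluded)

  exposures <- iv[c("player_id", "end_date", "twelve_month_matches",
                    "twelve_month_fge", "one_month_fge")]
  names(exposures)[2] <- "eval_date"

  iv <- stage("standardize", {
    cont <- intersect(c("age_years", "height_cm", "mass_kg",
                        "prev_injury_count", "one_month_fge"),
                      c(covs, "one_month_fge"))
    standardize_2sd(iv, cont)
  })
  iv$twelve_month_quartile <- stage("quartiles",
    assign_quartile(iv$twelve_month_matches,
                    breaks = mcfg$quartile_breaks %||%
                      quartile_breakpoints(iv$twelve_month_matches)))

  deg_cfg <- mcfg$twelve_month_degree %||% 3
  poly_tab <- NULL
  deg <- stage("polynomial", {
    if (identical(deg_cfg, "select")) {
      ps <- polynomial_select(iv, "twelve_month_matches",
                              adjust = reformulate(covs), ties = ties)
      poly_tab <- ps$table
      ps$degree
    } else as.integer(deg_cfg)
  })

  form <- reformulate(c(covs, sprintf("poly_c(twelve_month_matches, %d)", deg),
                        "one_month_fge"))
  fits <- stage("fit", {
    out <- lapply(randoms, function(r) {
      fit_frailty(iv, form, random = r, ties = ties)
    })
    names(out) <- randoms
    out
  })
  headline <- fits[[if ("team_player" %in% randoms) "team_player"
                    else length(fits)]]
  say("fit: headline model '%s', logLik %.2f, sigma2 = (%s)",
      headline$random, headline$loglik[["integrated"]],
      paste(sprintf("%.3f", headline$sigma2[!is.na(headline$sigma2)]),
            collapse = ", "))

  fit_tab <- dplyr::bind_rows(lapply(names(headline$coefficients),
                                     function(tm) hr_per_2sd(headline, tm)))
  comparison <- if (length(fits) >= 2L) {
    stage("compare", compare_models(fits))
  } else NULL
  mbi <- stage("mbi", mbi_table(fit_tab))
  curve <- stage("curve", hr_curve(headline, "twelve_month_matches"))

  inter <- NULL
  if (isTRUE(mcfg$interaction)) {
    inter <- stage("interaction", interaction_fit(
      iv, exposure = "one_month_fge", quartile = "twelve_month_quartile",
      adjust = reformulate(covs), random = headline$random, ties = ties))
  }

  # ---- stage outputs, then move atomically --------------------------------
  staging <- paste0(out_dir, ".staging-", Sys.getpid())
  if (dir.exists(staging)) unlink(staging, recursive = TRUE)
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)

  wr <- function(x, f) {
    readr::write_csv(x, file.path(staging, f), progress = FALSE)
    f
  }
  written <- c(
    wr(exposures, "exposures.csv"),
    wr(iv, "intervals.csv"),
    wr(fit_tab, "fit.csv"),
    if (!is.null(comparison)) wr(comparison$table, "comparison.csv"),
    if (!is.null(comparison)) wr(comparison$tests, "comparison_tests.csv"),
    wr(mbi, "mbi.csv"),
    wr(as_tibble(curve), "hr_curve.csv"),
    if (!is.null(poly_tab)) wr(poly_tab, "poly_selection.csv"),
    if (!is.null(inter)) wr(inter$table, "interaction.csv")
  )

  manifest <- list(
    package = "matchrisk",
    version = as.character(utils::packageVersion("matchrisk")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = unname(md5_of_object(config)),
    seed = cohort_cfg$seed %||% NA,
    input_digests = as.list(input_digests),
    n_players = nrow(cohort$players), n_injuries = nrow(cohort$injuries),
    n_intervals = nrow(iv), n_events = sum(iv$event),
    n_excluded_zero_exposure = n_excluded,
    headline_random = headline$random,
    convergence = headline$convergence[c("outer_evals", "outer_code",
                                         "grad_norm")],
    outputs = as.list(setNames(
      unname(tools::md5sum(file.path(staging, written))), written))
  )
  jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  written <- c(written, "manifest.json")

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ok <- file.copy(file.path(staging, written), file.path(out_dir, written),
                  overwrite = TRUE)
  if (!all(ok)) {
    abort("pipeline stage 'write': could not move outputs into place",
          class = c("matchrisk_pipeline_error", "matchrisk_error"))
  }
  say("wrote %d files to %s", length(written), out_dir)
  invisible(list(cohort = cohort, intervals = iv, fits = fits,
                 headline = headline, fit_table = fit_tab,
                 comparison = comparison, mbi = mbi, curve = curve,
                 interaction = inter, manifest = manifest))
}

# sim args may come from YAML with numbers parsed as doubles/strings
as_sim_args <- function(x) {
  if (!is.null(x$study_start)) x$study_start <- as.Date(x$study_start)
  for (nm in intersect(names(x), c("hr_2sd", "two_sd"))) {
    x[[nm]] <- unlist(x[[nm]])
  }
  for (nm in intersect(names(x), c("interaction_hr_ratio", "quartile_breaks",
                                   "twelve_month_coefs", "p_play_shape"))) {
    x[[nm]] <- as.numeric(unlist(x[[nm]]))
  }
  x
}

md5_of_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)   # scratch file only; hashed then removed
  tools::md5sum(f)
}
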