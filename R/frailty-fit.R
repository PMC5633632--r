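#' Control parameters for frailty model fitting
#'
#' @param inner_reltol relative change in the penalized partial likelihood at
#'   which the inner Newton-Raphson (over fixed effects and frailty modes at
#'   fixed variances) stops.
#' @param inner_maxit maximum inner Newton iterations.
#' @param outer_reltol relative convergence tolerance of the outer
#'   derivative-free search over log variance components.
#' @param outer_maxit maximum outer objective evaluations.
#' @param em_init number of fixed-point (posterior mean + curvature) variance
#'   updates used to initialise the outer search.
#' @param sigma2_init starting value for free variance components.
#' @param fix_variance optional named vector (names among `"team"`,
#'   `"player"`) of variance components to hold fixed rather than estimate;
#'   a component fixed at 0 removes its random effects entirely.
#' @param variance_se compute standard errors of the variance components from
#'   the numerically differentiated outer Hessian (adds a few objective
#'   evaluations).
#' @export
frailty_control <- function(inner_reltol = 1e-8, inner_maxit = 50L,
                            outer_reltol = 1e-6, outer_maxit = 100L,
                            em_init = 3L, sigma2_init = 0.1,
                            fix_variance = NULL, variance_se = TRUE) {
  if (!is.null(fix_variance)) {
    if (is.null(names(fix_variance)) ||
        !all(names(fix_variance) %in% c("team", "player")) ||
        any(fix_variance < 0)) {
      stop_validation("fix_variance must be a named non-negative vector with names in {team, player}")
    }
  }
  list(inner_reltol = inner_reltol, inner_maxit = as.integer(inner_maxit),
       outer_reltol = outer_reltol, outer_maxit = as.integer(outer_maxit),
       em_init = as.integer(em_init), sigma2_init = sigma2_init,
       fix_variance = fix_variance, variance_se = variance_se)
}

#' Proportional-hazards fits with nested log-normal frailties
#'
#' Fits the recurrent-event gap-time hazard model
#' \deqn{\lambda_{ij}(t) = \lambda_0(t) \exp(x_{ij}'\beta + u_i + v_{ij})}
#' for player j of team i, where \eqn{u_i \sim N(0, \sigma^2_{team})} and
#' \eqn{v_{ij} \sim N(0, \sigma^2_{player})} are Gaussian random intercepts on
#' the log hazard (log-normal frailties) capturing within-team and
#' within-player correlation of recurrent injury gap times. Estimation
#' maximises the penalized partial likelihood
#' \eqn{PPL(\beta, b) = \ell_{cox}(X\beta + Zb) - b'\Sigma^{-1}b/2}
#' over \eqn{(\beta, b)} by Newton-Raphson at fixed variances (monotone by
#' step-halving), inside a derivative-free search over the log variances that
#' maximises the Laplace-approximate integrated log-likelihood
#' \eqn{\ell_{int} = PPL(\hat\beta,\hat b)
#'   - \tfrac12 \log\det(\Sigma^{1/2} K_{bb} \Sigma^{1/2} + I)}
#' with \eqn{K_{bb}} the frailty block of the negative partial-likelihood
#' Hessian at the mode. With `random = "none"` the fit reduces exactly to the
#' Cox proportional-hazards model; with `random = "player"` to the shared
#' (within-player) frailty model.
#'
#' The data must carry the risk-interval columns `duration_hours` (the
#' gap-time survival axis), `event`, `team_id` and `player_id`; covariates
#' are taken from `formula` (right-hand side only), which may include
#' [poly_c()] terms for non-linear exposure effects and factor interactions.
#'
#' @param data risk-interval tibble from [build_intervals()] (typically after
#'   [standardize_2sd()]).
#' @param formula one-sided covariate formula, e.g.
#'   `~ age_years + position + poly_c(twelve_month_matches, 3)`.
#' @param random random-effect structure: `"team_player"` (nested, default),
#'   `"player"` (shared), `"team"`, or `"none"` (Cox PH).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param offset optional name of a column added to the linear predictor
#'   (e.g. `log_exposure_offset` for the calendar-time axis).
#' @param control a [frailty_control()] list.
#' @return an object of class `frailty_fit`; see [tidy.frailty_fit()],
#'   [glance.frailty_fit()], [hr_per_2sd()], [hr_curve()],
#'   [variance_test()] and [compare_models()].
#' @examples
#' b <- simulate_cohort(sim_config(n_teams = 4, players_per_team = 10,
#'                                 n_seasons = 1), seed = 7)
#' iv <- build_intervals(b, quiet = TRUE)
#' iv <- standardize_2sd(iv, c("age_years", "one_month_fge"))
#' f <- fit_frailty(iv, ~ age_years + one_month_fge, random = "player",
#'                  control = frailty_control(variance_se = FALSE))
#' glance(f)
#' @export
fit_frailty <- function(data, formula,
                        random = c("team_player", "player", "team", "none"),
                        ties = c("efron", "breslow"), offset = NULL,
                        control = frailty_control()) {
  random <- match.arg(random)
  ties <- match.arg(ties)
  need <- c("duration_hours", "event", "team_id", "player_id")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop_validation(sprintf("data lacks risk-interval column(s): %s",
                            paste(miss, collapse = ", ")))
  }

  ff <- stats::as.formula(formula)
  tt <- terms(ff, data = data)
  attr(tt, "intercept") <- 1L   # keep for factor contrasts, dropped below
  mf <- model.frame(tt, data)
  X <- model.matrix(tt, mf)
  asgn <- attr(X, "assign")
  keep <- asgn != 0L
  X <- X[, keep, drop = FALSE]
  asgn <- asgn[keep]
  if (nrow(X) != nrow(data)) {
    stop_validation("missing values in model covariates")
  }
  if (ncol(X)) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      stop_validation(sprintf(
        "collinear design: column(s) %s are linearly dependent",
        paste(colnames(X)[qrX$pivot[-seq_len(qrX$rank)]], collapse = ", ")))
    }
  }

  comps <- switch(random,
    none = character(0), team = "team", player = "player",
    team_player = c("team", "player"))
  fixv <- control$fix_variance
  fixed0 <- names(fixv)[!is.na(fixv) & fixv == 0]
  comps_active <- setdiff(comps, fixed0)      # components with effects present
  free <- setdiff(comps_active, names(fixv))  # components to estimate
  if ("team" %in% comps_active &&
      length(unique(data$team_id)) < 2L) {
    stop_validation("a team random effect needs at least 2 teams")
  }

  off <- if (!is.null(offset)) data[[offset]] else NULL
  # counting-process segments (weekly covariate updates) carry explicit
  # (gap_start_hours, gap_stop_hours] at-risk spans; plain intervals enter at 0
  segmented <- all(c("gap_start_hours", "gap_stop_hours") %in% names(data))
  if (segmented) {
    stop_t <- data$gap_stop_hours
    start_t <- data$gap_start_hours
    status <- as.logical(data$event)
    # consecutive segments of one interval with identical design rows and no
    # offset change span one risk period with a constant linear predictor:
    # merging them leaves the partial likelihood exactly unchanged
    if ("interval_id" %in% names(data) && nrow(X) > 1L) {
      ord <- order(data$interval_id, start_t)
      same <- data$interval_id[ord][-1L] == data$interval_id[ord][-length(ord)] &
        start_t[ord][-1L] == stop_t[ord][-length(ord)] &
        rowSums(abs(X[ord[-1L], , drop = FALSE] -
                      X[ord[-length(ord)], , drop = FALSE])) == 0 &
        !status[ord][-length(ord)]
      if (!is.null(off)) {
        same <- same & off[ord][-1L] == off[ord][-length(ord)]
      }
      run <- cumsum(c(1L, as.integer(!same)))
      first <- ord[!duplicated(run)]
      last <- ord[rev(!duplicated(rev(run)))]
      keep_rows <- first
      stop_t <- stop_t[last]
      start_t <- start_t[first]
      status <- status[last]
      X <- X[first, , drop = FALSE]
      if (!is.null(off)) off <- off[first]
      data_ids <- data[first, c("team_id", "player_id")]
    } else {
      data_ids <- data[c("team_id", "player_id")]
    }
  } else {
    stop_t <- data$duration_hours
    start_t <- NULL
    status <- as.logical(data$event)
    data_ids <- data[c("team_id", "player_id")]
  }
  pr <- prep_cox(
    duration = stop_t, status = status, X = X,
    team = if ("team" %in% comps_active) data_ids$team_id else NULL,
    player = if ("player" %in% comps_active) data_ids$player_id else NULL,
    offset = off,
    start = start_t
  )
  p <- pr$p

  sigma2 <- setNames(rep(NA_real_, 2), c("team", "player"))
  sigma2[comps] <- 0
  sigma2[comps_active] <- control$sigma2_init
  if (!is.null(fixv)) sigma2[names(fixv)] <- fixv

  pen_from_sigma2 <- function(s2) {
    c(rep(0, p),
      if (pr$qt) rep(1 / s2[["team"]], pr$qt),
      if (pr$qp) rep(1 / s2[["player"]], pr$qp))
  }
  sigb_from_sigma2 <- function(s2) {
    c(if (pr$qt) rep(sqrt(s2[["team"]]), pr$qt),
      if (pr$qp) rep(sqrt(s2[["player"]]), pr$qp))
  }

  state <- new.env(parent = emptyenv())
  state$theta <- NULL
  state$derivs <- NULL   # Cox derivatives at state$theta (penalty-free)
  state$evals <- 0L
  objective <- function(ls2_free) {
    s2 <- sigma2
    s2[free] <- exp(ls2_free)
    inner <- ppl_newton(pr, pen_from_sigma2(s2), theta0 = state$theta,
                        ties = ties, reltol = control$inner_reltol,
                        maxit = control$inner_maxit, derivs0 = state$derivs)
    state$theta <- inner$theta
    state$derivs <- inner$derivs
    state$evals <- state$evals + 1L
    laplace_loglik(inner, pr, sigb_from_sigma2(s2))
  }

  outer_conv <- 0L
  if (length(free)) {
    # fixed-point initialisation: sigma2 <- (sum b^2 + sum posterior var)/q
    ls2 <- log(pmax(sigma2[free], 1e-4))
    for (it in seq_len(control$em_init)) {
      s2 <- sigma2
      s2[free] <- exp(ls2)
      inner <- ppl_newton(pr, pen_from_sigma2(s2), theta0 = state$theta,
                          ties = ties, reltol = control$inner_reltol,
                          maxit = control$inner_maxit, derivs0 = state$derivs)
      state$theta <- inner$theta
      state$derivs <- inner$derivs
      Hp <- inner$derivs$negH
      diag(Hp) <- diag(Hp) + pen_from_sigma2(s2)
      Vd <- diag(chol2inv(chol(Hp)))
      upd <- vapply(free, function(cmp) {
        ib <- if (cmp == "team") p + seq_len(pr$qt) else p + pr$qt + seq_len(pr$qp)
        (sum(inner$theta[ib]^2) + sum(Vd[ib])) / length(ib)
      }, numeric(1))
      ls2 <- log(pmax(pmin(upd, 20), 1e-5))
    }
    lo <- log(1e-5); hi <- log(20)
    if (length(free) == 1L) {
      op <- optimize(function(x) -objective(pmin(pmax(x, lo), hi)),
                     interval = c(lo, hi), tol = 1e-4)
      ls2_hat <- op$minimum
    } else {
      op <- optim(ls2, function(x) -objective(pmin(pmax(x, lo), hi)),
                  method = "Nelder-Mead",
                  control = list(reltol = control$outer_reltol,
                                 maxit = control$outer_maxit))
      ls2_hat <- pmin(pmax(op$par, lo), hi)
      outer_conv <- op$convergence
    }
    sigma2[free] <- exp(ls2_hat)
  }

  # final inner solve at the selected variances
  pen <- pen_from_sigma2(sigma2)
  inner <- ppl_newton(pr, pen, theta0 = state$theta, ties = ties,
                      reltol = control$inner_reltol,
                      maxit = control$inner_maxit, derivs0 = state$derivs)
  state$derivs <- inner$derivs
  l_int <- laplace_loglik(inner, pr, sigb_from_sigma2(sigma2))
  theta <- inner$theta
  Hp <- inner$derivs$negH
  diag(Hp) <- diag(Hp) + pen
  V <- if (pr$d) chol2inv(chol(Hp)) else matrix(0, 0, 0)

  # variance-component SEs from the numerically differentiated outer Hessian
  sigma2_se <- setNames(rep(NA_real_, 2), c("team", "player"))
  if (control$variance_se && length(free)) {
    h <- 0.1
    ls2_hat <- log(sigma2[free])
    f0 <- l_int
    k <- length(free)
    Ho <- matrix(NA_real_, k, k)
    fp <- fm <- numeric(k)
    for (i in seq_len(k)) {
      ei <- replace(numeric(k), i, h)
      fp[i] <- objective(ls2_hat + ei)
      fm[i] <- objective(ls2_hat - ei)
      Ho[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h^2
    }
    if (k == 2L) {
      fpp <- objective(ls2_hat + c(h, h))
      fmm <- objective(ls2_hat - c(h, h))
      fpm <- objective(ls2_hat + c(h, -h))
      fmp <- objective(ls2_hat + c(-h, h))
      Ho[1, 2] <- Ho[2, 1] <- (fpp - fpm - fmp + fmm) / (4 * h^2)
    }
    vc <- tryCatch(solve(-Ho), error = function(e) NULL)
    if (!is.null(vc) && all(diag(vc) > 0)) {
      sigma2_se[free] <- sigma2[free] * sqrt(diag(vc))  # delta method
    } else {
      warn("outer Hessian not positive definite; variance-component SEs unavailable (boundary estimate?)")
    }
    # restore the inner state at the optimum
    inner <- ppl_newton(pr, pen, theta0 = state$theta, ties = ties,
                        reltol = control$inner_reltol,
                        maxit = control$inner_maxit, derivs0 = state$derivs)
  }

  beta <- setNames(theta[seq_len(p)], pr$xnames)
  se_beta <- setNames(sqrt(diag(V)[seq_len(p)]), pr$xnames)
  frail <- list()
  if (pr$qt) {
    frail$team <- tibble(team_id = pr$team_levels,
                         mode = theta[p + seq_len(pr$qt)])
  }
  if (pr$qp) {
    frail$player <- tibble(player_id = pr$player_levels,
                           mode = theta[p + pr$qt + seq_len(pr$qp)])
  }

  df <- p + length(free)
  ll <- if (length(comps_active)) l_int else inner$loglik
  structure(list(
    call = match.call(), formula = ff, terms = attr(mf, "terms"),
    xlevels = stats::.getXlevels(tt, mf), assign = asgn,
    random = random, ties = ties, control = control,
    coefficients = beta, se = se_beta,
    vcov = structure(V[seq_len(p), seq_len(p), drop = FALSE],
                     dimnames = list(pr$xnames, pr$xnames)),
    sigma2 = sigma2, sigma2_se = sigma2_se,
    frailty = frail,
    loglik = c(integrated = ll, penalized = inner$ppl,
               partial = inner$loglik),
    df = df,
    aic = -2 * ll + 2 * df,
    bic = -2 * ll + df * log(pr$n_events),
    n_events = pr$n_events, n_intervals = pr$n,
    convergence = list(
      outer_evals = state$evals, outer_code = outer_conv,
      inner_iterations = inner$iterations, grad_norm = inner$grad_norm,
      ppl_trace = inner$trace
    ),
    scale_report = attr(data, "scale_report"),
    data = data,
    fingerprint = c(n = pr$n, events = pr$n_events,
                    dursum = sum(data$duration_hours))
  ), class = "frailty_fit")
}

#' @export
print.frailty_fit <- function(x, ...) {
  lab <- switch(x$random,
    none = "Cox proportional hazards (no frailty)",
    player = "shared frailty (player)",
    team = "shared frailty (team)",
    team_player = "nested frailty (team / player)")
  cat(sprintf("<frailty_fit> %s, %s ties\n", lab, x$ties))
  cat(sprintf("  %d intervals, %d events\n", x$n_intervals, x$n_events))
  if (length(x$coefficients)) {
    print(tidy(x, exponentiate = TRUE), n = 20)
  }
  s2 <- x$sigma2[!is.na(x$sigma2)]
  if (length(s2)) {
    cat("  variance components:",
        paste(sprintf("sigma2_%s = %.4f", names(s2), s2), collapse = ", "),
        "\n")
  }
  cat(sprintf("  integrated logLik %.3f | AIC %.1f | BIC %.1f\n",
              x$loglik[["integrated"]], x$aic, x$bic))
  invisible(x)
}

#' @export
logLik.frailty_fit <- function(object, ...) {
  structure(object$loglik[["integrated"]], df = object$df,
            nobs = object$n_events, class = "logLik")
}

#' Tidy a frailty fit
#'
#' Broom-style one-row-per-term summary. Confidence intervals are on the
#' hazard-ratio scale when `exponentiate = TRUE` and use the normal quantile
#' of `conf.level` (90% by default, the conventional level for
#' magnitude-based inference on hazard ratios).
#'
#' @param x a `frailty_fit`.
#' @param exponentiate report `exp(beta)` (hazard ratios) instead of log
#'   hazard ratios.
#' @param conf.level confidence level (default 0.90).
#' @param ... unused.
#' @method tidy frailty_fit
#' @export
tidy.frailty_fit <- function(x, exponentiate = FALSE, conf.level = 0.90,
                             ...) {
  z <- qnorm(1 - (1 - conf.level) / 2)
  est <- x$coefficients
  se <- x$se
  out <- tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pnorm(-abs(unname(est / se))),
    conf.low = unname(est - z * se), conf.high = unname(est + z * se)
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' Glance at a frailty fit
#'
#' @param x a `frailty_fit`.
#' @param ... unused.
#' @method glance frailty_fit
#' @export
glance.frailty_fit <- function(x, ...) {
  tibble(
    random = x$random,
    logLik = x$loglik[["integrated"]],
    logLik_partial = x$loglik[["partial"]],
    AIC = x$aic, BIC = x$bic, df = x$df,
    sigma2_team = x$sigma2[["team"]], sigma2_player = x$sigma2[["player"]],
    n_events = x$n_events, n_intervals = x$n_intervals,
    outer_evals = x$convergence$outer_evals,
    converged = x$convergence$outer_code == 0L
  )
}
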