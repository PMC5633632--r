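#' Hazard ratio per two-standard-deviation increase
#'
#' Extracts `exp(beta)` and its confidence interval for one model term. When
#' the covariate was rescaled with [standardize_2sd()] before fitting, a unit
#' change on the model scale is a 2-SD change on the original scale, so the
#' returned hazard ratio reads directly as "per 2 SD". The interval uses
#' `exp(beta +/- z * se)` with `z = qnorm(0.95) = 1.6449` at the default 90%
#' level.
#'
#' @param fit a `frailty_fit`.
#' @param term model term name (a column of the design matrix).
#' @param conf.level confidence level, default 0.90.
#' @return one-row tibble: `term`, `hr`, `ci_low`, `ci_high`, `beta`, `se`.
#' @export
hr_per_2sd <- function(fit, term, conf.level = 0.90) {
  stopifnot(inherits(fit, "frailty_fit"))
  if (!term %in% names(fit$coefficients)) {
    stop_validation(sprintf(
      "term '%s' is not in the model (have: %s)", term,
      paste(names(fit$coefficients), collapse = ", ")))
  }
  z <- qnorm(1 - (1 - conf.level) / 2)
  b <- fit$coefficients[[term]]
  se <- fit$se[[term]]
  tibble(term = term, hr = exp(b), ci_low = exp(b - z * se),
         ci_high = exp(b + z * se), beta = b, se = se)
}

find_covariate_term <- function(fit, covariate) {
  labs <- attr(fit$terms, "term.labels")
  hit <- vapply(labs, function(l) {
    v <- all.vars(str2lang(l))
    covariate %in% v && !grepl(":", l, fixed = TRUE)
  }, logical(1))
  if (!any(hit)) {
    stop_validation(sprintf("covariate '%s' is not a main-effect term of the model",
                            covariate))
  }
  labs[hit]
}

#' Hazard-ratio curve over an exposure grid
#'
#' Evaluates `HR(x) = exp(p(x) - p(x_ref))` for a (possibly polynomial)
#' covariate term, with delta-method confidence bands from the coefficient
#' covariance. The reference is the covariate mean by default, where the
#' curve is exactly 1 with a zero-width interval. Grid points outside the
#' fitted data range are flagged as extrapolation.
#'
#' @param fit a `frailty_fit`.
#' @param covariate name of the underlying data column (e.g.
#'   `"twelve_month_matches"`), whether it enters linearly or through
#'   [poly_c()].
#' @param grid numeric grid of covariate values; defaults to 100 points over
#'   the observed range.
#' @param ref reference value (default: observed mean).
#' @param conf.level confidence level for the bands (default 0.90).
#' @return a tibble of class `hr_curve`: `x`, `hr`, `ci_low`, `ci_high`,
#'   `extrapolated`; plot with [autoplot()].
#' @export
hr_curve <- function(fit, covariate, grid = NULL, ref = NULL,
                     conf.level = 0.90) {
  stopifnot(inherits(fit, "frailty_fit"))
  find_covariate_term(fit, covariate)  # errors if absent
  xobs <- fit$data[[covariate]]
  if (is.null(xobs)) {
    stop_validation(sprintf("fit data has no column '%s'", covariate))
  }
  rng <- range(xobs)
  if (is.null(grid)) grid <- seq(rng[1], rng[2], length.out = 100)
  ref <- ref %||% mean(xobs)
  if (any(grid < rng[1] | grid > rng[2])) {
    warn("hr_curve: grid extends beyond the observed covariate range (extrapolation)")
  }

  newdata <- fit$data[rep(1L, length(grid) + 1L), , drop = FALSE]
  newdata[[covariate]] <- c(grid, ref)
  tt <- delete.response(fit$terms)
  mfn <- model.frame(tt, newdata, xlev = fit$xlevels)
  Xn <- model.matrix(tt, mfn)
  Xn <- Xn[, colnames(Xn) %in% names(fit$coefficients), drop = FALSE]
  Xn <- Xn[, names(fit$coefficients), drop = FALSE]
  D <- Xn[seq_along(grid), , drop = FALSE] -
    matrix(Xn[length(grid) + 1L, ], length(grid), ncol(Xn), byrow = TRUE)
  eta <- as.numeric(D %*% fit$coefficients)
  v <- as.numeric(rowSums((D %*% fit$vcov) * D))
  z <- qnorm(1 - (1 - conf.level) / 2)
  se <- sqrt(pmax(v, 0))
  out <- tibble(
    x = grid, hr = exp(eta),
    ci_low = exp(eta - z * se), ci_high = exp(eta + z * se),
    extrapolated = grid < rng[1] | grid > rng[2]
  )
  attr(out, "covariate") <- covariate
  attr(out, "ref") <- ref
  class(out) <- c("hr_curve", class(out))
  out
}

#' @method autoplot hr_curve
#' @export
autoplot.hr_curve <- function(object, benefit = 0.90, harm = 1.11, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$hr)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = benefit, ymax = harm, alpha = 0.15) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_continuous(trans = "log") +
    ggplot2::labs(x = attr(object, "covariate"),
                  y = sprintf("hazard ratio (ref = %.1f)", attr(object, "ref")))
}

#' Polynomial degree selection for a non-linear exposure effect
#'
#' Refits the model with linear, quadratic and cubic [poly_c()] bases for one
#' covariate and returns the selected degree together with the full
#' per-degree AIC/BIC table. Selection is parsimonious: among the candidate
#' degrees, the lowest one whose AIC lies within `aic_delta` (default 2, the
#' conventional substantiality threshold) of the minimum is chosen, so a
#' higher degree is only selected when it improves the fit substantially.
#'
#' @param data risk-interval tibble.
#' @param covariate covariate to expand.
#' @param adjust one-sided formula of adjustment terms kept in every fit
#'   (default none).
#' @param max_degree highest degree tried (1–3).
#' @param aic_delta substantiality margin for preferring a lower degree.
#' @inheritParams fit_frailty
#' @return list of class `poly_selection` with elements `degree` (the
#'   AIC-best degree), `table` (degree, logLik, df, AIC, BIC) and `fits`.
#' @export
polynomial_select <- function(data, covariate, adjust = NULL,
                              random = "none", ties = "efron",
                              control = frailty_control(variance_se = FALSE),
                              max_degree = 3, aic_delta = 2) {
  adj <- if (is.null(adjust)) character(0) else
    attr(terms(stats::as.formula(adjust)), "term.labels")
  degs <- seq_len(max_degree)
  fits <- lapply(degs, function(d) {
    f <- reformulate(c(adj, sprintf("poly_c(%s, %d)", covariate, d)))
    fit_frailty(data, f, random = random, ties = ties, control = control)
  })
  tab <- dplyr::bind_rows(lapply(seq_along(degs), function(i) {
    g <- fits[[i]]
    tibble(degree = degs[i], logLik = g$loglik[["integrated"]],
           df = g$df, AIC = g$aic, BIC = g$bic)
  }))
  best <- min(tab$degree[tab$AIC <= min(tab$AIC) + aic_delta])
  structure(list(degree = best, table = tab, fits = fits),
            class = "poly_selection")
}

#' @export
print.poly_selection <- function(x, ...) {
  cat(sprintf("<poly_selection> selected degree: %d\n", x$degree))
  print(x$table)
  invisible(x)
}

#' Exposure-quartile interaction with recent workload
#'
#' Fits the multiplicative interaction between the chronic-load quartile
#' (`quartile` column, reference = lowest quartile) and a continuous recent
#' workload term, and reports, per quartile, the hazard ratio of the
#' continuous term within that quartile together with its ratio to the
#' reference-quartile effect (the interaction contrast, the quantity usually
#' tabulated). Every quartile stratum must contain events.
#'
#' @param data risk-interval tibble with an assigned quartile column.
#' @param exposure continuous term name (typically the 2-SD-standardized
#'   1-month exposure).
#' @param quartile name of the quartile factor column.
#' @param adjust one-sided formula of adjustment terms.
#' @param conf.level confidence level (default 0.90).
#' @inheritParams fit_frailty
#' @return list of class `quartile_interaction`: `table` (per-quartile
#'   within-stratum HR and ratio-to-reference with CIs and event counts) and
#'   `fit` (the underlying `frailty_fit`).
#' @export
interaction_fit <- function(data, exposure = "one_month_fge",
                            quartile = "twelve_month_quartile",
                            adjust = NULL, random = "team_player",
                            ties = "efron",
                            control = frailty_control(variance_se = FALSE),
                            conf.level = 0.90) {
  qcol <- data[[quartile]]
  if (is.null(qcol)) {
    stop_validation(sprintf("no quartile column '%s'; run assign_quartile() first",
                            quartile))
  }
  qcol <- droplevels(factor(qcol))
  ev_by_q <- tapply(data$event, qcol, sum)
  if (any(is.na(ev_by_q)) || any(ev_by_q == 0)) {
    bad <- names(ev_by_q)[is.na(ev_by_q) | ev_by_q == 0]
    stop_validation(sprintf("quartile stratum with no events: %s",
                            paste(bad, collapse = ", ")))
  }
  adj <- if (is.null(adjust)) character(0) else
    attr(terms(stats::as.formula(adjust)), "term.labels")
  f <- reformulate(c(adj, exposure, quartile,
                     sprintf("%s:%s", exposure, quartile)))
  fit <- fit_frailty(data, f, random = random, ties = ties, control = control)

  z <- qnorm(1 - (1 - conf.level) / 2)
  cn <- names(fit$coefficients)
  b <- fit$coefficients
  V <- fit$vcov
  levs <- levels(qcol)
  main <- exposure
  rows <- lapply(seq_along(levs), function(k) {
    lev <- levs[k]
    if (k == 1L) {
      ct <- setNames(numeric(length(cn)), cn)
      ct[main] <- 1
      int_name <- NA_character_
    } else {
      int_name <- cn[grepl(paste0(quartile, lev), cn, fixed = TRUE) &
                       grepl(main, cn, fixed = TRUE) &
                       grepl(":", cn, fixed = TRUE)]
      if (length(int_name) != 1L) {
        stop_validation(sprintf("cannot locate interaction column for level %s", lev))
      }
      ct <- setNames(numeric(length(cn)), cn)
      ct[main] <- 1
      ct[int_name] <- 1
    }
    bw <- sum(ct * b)
    sew <- sqrt(drop(t(ct) %*% V %*% ct))
    if (k == 1L) {
      ratio <- 1; rlo <- NA_real_; rhi <- NA_real_
    } else {
      br <- b[[int_name]]
      ser <- fit$se[[int_name]]
      ratio <- exp(br); rlo <- exp(br - z * ser); rhi <- exp(br + z * ser)
    }
    tibble(quartile = lev,
           hr_within = exp(bw), within_low = exp(bw - z * sew),
           within_high = exp(bw + z * sew),
           hr_ratio = ratio, ratio_low = rlo, ratio_high = rhi,
           n_events = unname(ev_by_q[lev]))
  })
  structure(list(table = dplyr::bind_rows(rows), fit = fit),
            class = "quartile_interaction")
}

#' @export
print.quartile_interaction <- function(x, ...) {
  cat("<quartile_interaction> effect of recent exposure within chronic-load quartiles\n")
  print(x$table)
  invisible(x)
}

#' Tests of a frailty variance component against zero
#'
#' Two complementary tests of \eqn{H_0: \sigma^2 = 0}:
#' \itemize{
#'   \item a one-sided Wald-type test, \eqn{z = \hat\sigma^2 / SE(\hat\sigma^2)}
#'     with \eqn{p = 1 - \Phi(z)}, using the delta-method SE from the outer
#'     Hessian (a pragmatic boundary-aware screen);
#'   \item a likelihood-ratio test against the refitted model without the
#'     component, referred to the boundary 50:50 mixture
#'     \eqn{\tfrac12\chi^2_0 + \tfrac12\chi^2_1}, i.e.
#'     \eqn{p = \tfrac12 P(\chi^2_1 \ge LR)} (0.5 at LR = 0).
#' }
#' Both are reported because the exact form of published "modified Wald"
#' variance tests varies between software implementations.
#'
#' @param fit a `frailty_fit` with the component present.
#' @param component `"player"` or `"team"`.
#' @return one-row tibble with both statistics and p-values.
#' @export
variance_test <- function(fit, component = c("player", "team")) {
  component <- match.arg(component)
  stopifnot(inherits(fit, "frailty_fit"))
  s2 <- fit$sigma2[[component]]
  if (is.na(s2)) {
    stop_validation(sprintf("model has no %s variance component", component))
  }
  se <- fit$sigma2_se[[component]]
  wald <- if (is.na(se) || se <= 0) NA_real_ else s2 / se
  wald_p <- if (is.na(wald)) NA_real_ else pnorm(wald, lower.tail = FALSE)

  reduced_random <- switch(fit$random,
    team_player = if (component == "team") "player" else "team",
    player = "none", team = "none",
    stop_validation("variance_test needs a model with random effects"))
  red <- fit_frailty(fit$data, fit$formula, random = reduced_random,
                     ties = fit$ties,
                     control = utils::modifyList(fit$control,
                                                 list(variance_se = FALSE)))
  lr <- max(0, 2 * (fit$loglik[["integrated"]] - red$loglik[["integrated"]]))
  lr_p <- 0.5 * pchisq(lr, df = 1, lower.tail = FALSE)
  tibble(component = component, sigma2 = s2, se = se,
         wald_statistic = wald, wald_p = wald_p,
         lr_statistic = lr, lr_p = lr_p)
}

#' Compare Cox PH, shared and nested frailty fits
#'
#' Builds the model-selection table (integrated log-likelihood, AIC
#' `-2 LL + 2k`, BIC `-2 LL + k log(n_events)`, with `k` counting fixed
#' effects plus estimated variance components) and all pairwise
#' likelihood-ratio tests. Tests that add variance components use boundary
#' chi-square mixtures: \eqn{p = \tfrac12 P(\chi^2_1 \ge LR)} for one added
#' component and \eqn{p = \tfrac12 P(\chi^2_1 \ge LR) +
#' \tfrac14 P(\chi^2_2 \ge LR)} for two (point-mass terms dropped, so a zero
#' statistic gives p = 0.5, the documented convention). Differences in AIC or
#' BIC larger than 2 are flagged as substantial; LR p-values at or below 0.10
#' as significant.
#'
#' @param ... two or more `frailty_fit` objects on the identical interval set
#'   and fixed-effect specification (optionally named).
#' @param alpha significance level for the LR flag (default 0.10).
#' @param aic_delta substantiality threshold for |dAIC|, |dBIC| (default 2).
#' @return list of class `model_comparison`: `table` and `tests` tibbles.
#' @export
compare_models <- function(..., alpha = 0.10, aic_delta = 2) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1L]]) &&
      !inherits(fits[[1L]], "frailty_fit")) {
    fits <- fits[[1L]]
  }
  stopifnot(length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1), "frailty_fit")))
  labs <- names(fits)
  auto <- vapply(fits, function(f) switch(f$random,
    none = "Cox PH", player = "Shared frailty (player)",
    team = "Shared frailty (team)",
    team_player = "Nested frailty (team/player)"), character(1))
  if (is.null(labs)) labs <- auto else labs[labs == ""] <- auto[labs == ""]

  fp <- vapply(fits, function(f) f$fingerprint, numeric(3))
  if (any(apply(fp, 1, function(r) max(abs(r - r[1]))) > 1e-8)) {
    stop_validation("fits were not made on the identical interval set")
  }
  np <- vapply(fits, function(f) length(f$coefficients), integer(1))
  if (length(unique(np)) != 1L) {
    stop_validation("fits do not share the fixed-effect specification")
  }

  tab <- dplyr::bind_rows(lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    tibble(model = labs[i], random = f$random, df = f$df,
           logLik = f$loglik[["integrated"]], AIC = f$aic, BIC = f$bic)
  }))
  tab$delta_AIC <- tab$AIC - min(tab$AIC)
  tab$delta_BIC <- tab$BIC - min(tab$BIC)

  nvc <- function(f) f$df - length(f$coefficients)
  pairs <- utils::combn(seq_along(fits), 2L)
  tests <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    # orient so model 2 is the richer one
    if (nvc(fits[[i1]]) > nvc(fits[[i2]])) { tmp <- i1; i1 <- i2; i2 <- tmp }
    lr <- max(0, 2 * (fits[[i2]]$loglik[["integrated"]] -
                        fits[[i1]]$loglik[["integrated"]]))
    dd <- nvc(fits[[i2]]) - nvc(fits[[i1]])
    p <- if (dd <= 1L) {
      0.5 * pchisq(lr, 1, lower.tail = FALSE)
    } else {
      0.5 * pchisq(lr, 1, lower.tail = FALSE) +
        0.25 * pchisq(lr, 2, lower.tail = FALSE)
    }
    tibble(model_null = labs[i1], model_alt = labs[i2],
           lr_statistic = lr, df_diff = dd, p = p,
           significant = p <= alpha,
           delta_AIC = fits[[i1]]$aic - fits[[i2]]$aic,
           delta_BIC = fits[[i1]]$bic - fits[[i2]]$bic,
           substantial_AIC = abs(fits[[i1]]$aic - fits[[i2]]$aic) > aic_delta,
           substantial_BIC = abs(fits[[i1]]$bic - fits[[i2]]$bic) > aic_delta)
  }))
  structure(list(table = tab, tests = tests, alpha = alpha,
                 aic_delta = aic_delta),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(x$table)
  cat(sprintf("pairwise likelihood-ratio tests (significant at p <= %.2f, substantial at |delta| > %g):\n",
              x$alpha, x$aic_delta))
  print(x$tests)
  invisible(x)
}
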