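# Numerical core of the proportional-hazards fits.
#
# Data are risk segments (start, stop] on the gap-time axis (plain gap
# intervals have start = 0) with an event flag at stop, a fixed-effect design
# matrix X (n x p) and optional team / player random-intercept indices. The
# coefficient layout is [beta (p) | team effects (qt) | player effects (qp)].
#
# cox_derivs() returns the Cox partial log-likelihood and its first two exact
# derivatives with respect to the full coefficient vector:
#   grad = A'(status - r * Lambda*)
#   -H   = A' diag(w) A - G'G
# where r = exp(eta), Lambda* is the (Breslow/Efron) cumulative hazard over
# each segment's at-risk span minus the Efron within-tie correction,
# w = r * Lambda*, and G holds one row per event step j of each tied-event
# group, (s - (j/d) s_D) / (S - (j/d) S_D), with S, s the risk-set sums of r
# and r*a at that event time. Risk-set sums with delayed entry are computed
# as suffix sums over a merged boundary list (stops add, starts subtract),
# which keeps every pass a set of vectorised cumulative sums: no O(n) R-level
# loop, only an O(q) loop to fill the random-effect columns of G. The cost
# per call is dominated by one dense crossprod of G (events x coefficients).

prep_cox <- function(duration, status, X, team = NULL, player = NULL,
                     offset = NULL, start = NULL) {
  n <- length(duration)
  stopifnot(length(status) == n, is.matrix(X), nrow(X) == n)
  if (!any(status)) stop_validation("no events: cannot fit a hazard model")
  if (any(!is.finite(duration)) || any(duration < 0)) {
    stop_validation("durations must be finite and non-negative")
  }
  start <- start %||% numeric(n)
  if (any(start < 0) || any(start > duration)) {
    stop_validation("segment entry times must lie in [0, stop]")
  }
  # adjudicate floating-point near-ties: times closer than sqrt(eps) on the
  # data scale are treated as equal (the survival package's convention), so
  # that sums computed in different orders still form proper tie groups
  ut <- sort(unique(c(duration, start)))
  if (length(ut) > 1L) {
    tol <- sqrt(.Machine$double.eps) * max(abs(ut), 1)
    cl <- cumsum(c(1L, as.integer(diff(ut) > tol)))
    if (cl[length(cl)] < length(ut)) {
      rep_val <- ut[!duplicated(cl)]
      duration <- rep_val[cl[match(duration, ut)]]
      start <- rep_val[cl[match(start, ut)]]
    }
  }
  if (any(status & duration <= start)) {
    stop_validation("event segments must have positive at-risk length")
  }
  p <- ncol(X)
  ti <- pi_ <- NULL
  team_lev <- player_lev <- NULL
  if (!is.null(team)) {
    tf <- factor(team)
    team_lev <- levels(tf)
    ti <- as.integer(tf)
  }
  if (!is.null(player)) {
    pf <- factor(player)
    player_lev <- levels(pf)
    pi_ <- as.integer(pf)
  }
  qt <- length(team_lev)
  qp <- length(player_lev)

  # event groups (tied event times), ascending
  ev <- which(status)
  gdur <- sort(unique(duration[ev]))
  m <- length(gdur)
  gid_ev <- match(duration[ev], gdur)         # group of each event row
  dsize <- tabulate(gid_ev, m)                # events per group
  ev_by_g <- split(ev, gid_ev)

  # merged boundary list: stops enter (+), positive starts leave (-)
  pos_start <- which(start > 0)
  bidx <- c(seq_len(n), pos_start)
  bsign <- c(rep(1, n), rep(-1, length(pos_start)))
  btime <- c(duration, start[pos_start])
  bord <- order(btime)
  # boundaries with time < each group time (suffix-sum split point)
  cut_g <- findInterval(gdur, btime[bord], left.open = TRUE)
  bidx_ord <- bidx[bord]
  bsign_ord <- bsign[bord]
  Xbord <- X[bidx_ord, , drop = FALSE] * bsign_ord

  # binned prefix-sum structure for the random-effect columns of G: every
  # boundary contributes to its team column and its player column; boundaries
  # are keyed by (event-group bin, column) so that one cumsum per derivative
  # call yields all risk-set sums at once
  q <- qt + qp
  zstruct <- NULL
  if (q) {
    bin <- findInterval(btime, gdur) + 1L           # 1 .. m+1
    zsrc <- integer(0); zcol <- integer(0)
    if (qt) { zsrc <- seq_along(bidx); zcol <- ti[bidx] }
    if (qp) {
      zsrc <- c(zsrc, seq_along(bidx))
      zcol <- c(zcol, qt + pi_[bidx])
    }
    zbin <- bin[zsrc]
    zkey <- (zbin - 1L) * q + zcol
    zord <- order(zkey)
    zkey_s <- zkey[zord]
    zends <- which(c(zkey_s[-1] != zkey_s[-length(zkey_s)], TRUE))
    ukey <- zkey_s[zends]
    zstruct <- list(
      src = zsrc[zord],            # boundary index feeding each slot
      ends = zends,                # run ends in sorted order
      # flat indices into the (m+1) x q bin matrix, column-major
      flat = ((ukey - 1L) %% q) * (m + 1L) + ((ukey - 1L) %/% q) + 1L
    )
  }

  # Efron/Breslow step expansion: one G row per (group, step)
  list(
    n = n, p = p, qt = qt, qp = qp, d = p + qt + qp,
    stop = duration, start = start, status = as.logical(status),
    X = X, ti = ti, pi = pi_, off = offset,
    ev = ev, gdur = gdur, m = m, gid_ev = gid_ev, dsize = dsize,
    ev_by_g = ev_by_g, tied_groups = which(dsize > 1L),
    bidx = bidx, bsign = bsign, btime = btime, bord = bord, cut_g = cut_g,
    bidx_ord = bidx_ord, bsign_ord = bsign_ord, Xbord = Xbord,
    cut0 = cut_g == 0L, zstruct = zstruct,
    n_events = length(ev),
    team_levels = team_lev, player_levels = player_lev,
    xnames = colnames(X)
  )
}

# suffix sums at the group times from a cumulative sum over time-ordered
# signed boundary values (cut = number of boundaries strictly earlier)
suffix_from_cumsum <- function(cs, cut, cut0) {
  v <- cs[length(cs)] - cs[pmax(cut, 1L)]
  v[cut0] <- cs[length(cs)]
  v
}

cox_derivs <- function(pr, theta, ties = "efron",
                       what = c("all", "loglik")) {
  what <- match.arg(what)
  efron <- identical(ties, "efron")
  p <- pr$p; qt <- pr$qt; qp <- pr$qp; d <- pr$d; n <- pr$n; m <- pr$m
  beta <- theta[seq_len(p)]
  eta <- if (p) drop(pr$X %*% beta) else numeric(n)
  if (qt) eta <- eta + theta[p + pr$ti]
  if (qp) eta <- eta + theta[p + qt + pr$pi]
  if (!is.null(pr$off)) eta <- eta + pr$off
  if (any(!is.finite(eta))) {
    stop_validation("non-finite linear predictor (possible separation)")
  }
  r <- exp(eta)

  svo <- pr$bsign_ord * r[pr$bidx_ord]   # signed boundary weights, by time
  S_g <- suffix_from_cumsum(cumsum(svo), pr$cut_g, pr$cut0)
  if (any(S_g <= 0)) {
    stop_validation("non-positive risk-set mass (numerical overflow?)")
  }
  rev_ <- r[pr$ev]
  Sd_g <- as.numeric(rowsum(rev_, pr$gid_ev, reorder = TRUE))

  # log-likelihood over Efron/Breslow steps
  ds <- pr$dsize
  if (efron) {
    rows_idx <- rep.int(seq_len(m), ds)
    fstep <- (sequence(ds) - 1) / ds[rows_idx]
  } else {
    rows_idx <- seq_len(m)
    fstep <- numeric(m)
  }
  den <- S_g[rows_idx] - fstep * Sd_g[rows_idx]
  loglik <- sum(eta[pr$ev]) -
    if (efron) sum(log(den)) else sum(ds * log(den))

  if (what == "loglik") {
    return(list(loglik = loglik))
  }

  # cumulative-hazard increments per group and Efron tie corrections
  if (efron) {
    c1inc <- as.numeric(rowsum(1 / den, rows_idx, reorder = TRUE))
    c2g <- as.numeric(rowsum(fstep / den, rows_idx, reorder = TRUE))
  } else {
    c1inc <- ds / den
    c2g <- numeric(m)
  }
  c1cum <- c(0, cumsum(c1inc))
  lam <- c1cum[findInterval(pr$stop, pr$gdur) + 1L] -
    c1cum[findInterval(pr$start, pr$gdur) + 1L]
  corr <- numeric(n)
  corr[pr$ev] <- c2g[pr$gid_ev]
  lamstar <- lam - corr
  res <- as.numeric(pr$status) - r * lamstar
  w <- r * lamstar

  # risk-set sum vectors s_g (one row per event group), normalized into G
  # column by column to keep large temporaries to a minimum
  q <- qt + qp
  notied <- !length(pr$tied_groups)
  if (notied) {
    G <- matrix(0, m, d)              # one row per group, divided by S_g
    den_g <- den
  } else if (efron) {
    SG <- matrix(0, m, d)             # unnormalized; expanded to steps below
  } else {
    G <- matrix(0, m, d)
    den_g <- den / sqrt(ds)           # Breslow: one row per group, weight d_g
  }
  fill <- function(k, colvals) {
    if (notied || !efron) G[, k] <<- colvals / den_g else SG[, k] <<- colvals
  }
  if (p) {
    for (j in seq_len(p)) {
      fill(j, suffix_from_cumsum(cumsum(pr$Xbord[, j] * r[pr$bidx_ord]),
                                 pr$cut_g, pr$cut0))
    }
  }
  if (q) {
    zs <- pr$zstruct
    sv <- pr$bsign * r[pr$bidx]
    cs <- cumsum(sv[zs$src])
    agg <- cs[zs$ends]
    if (length(agg) > 1L) {
      agg[-1L] <- agg[-1L] - cs[zs$ends[-length(zs$ends)]]
    }
    Q <- matrix(0, m + 1L, q)
    Q[zs$flat] <- agg
    for (k in seq_len(q)) {
      ck <- cumsum(Q[seq_len(m), k])
      fill(p + k, (ck[m] + Q[m + 1L, k]) - ck)
    }
  }
  if (!notied && efron) {
    G <- SG[rows_idx, , drop = FALSE]
    # subtract f * s_D for tied groups (f = 0 elsewhere)
    for (g in pr$tied_groups) {
      E <- pr$ev_by_g[[g]]
      sd_vec <- numeric(d)
      if (p) sd_vec[seq_len(p)] <- drop(crossprod(pr$X[E, , drop = FALSE], r[E]))
      if (qt) {
        tt <- rowsum(r[E], pr$ti[E])
        sd_vec[p + as.integer(rownames(tt))] <- tt[, 1]
      }
      if (qp) {
        pp <- rowsum(r[E], pr$pi[E])
        sd_vec[p + qt + as.integer(rownames(pp))] <- pp[, 1]
      }
      sel <- which(rows_idx == g)
      G[sel, ] <- G[sel, , drop = FALSE] -
        tcrossprod(fstep[sel], sd_vec)
    }
    G <- G / den
  }

  grad <- numeric(d)
  if (p) grad[seq_len(p)] <- drop(crossprod(pr$X, res))
  if (qt) {
    s <- rowsum(res, pr$ti)
    grad[p + as.integer(rownames(s))] <- s[, 1]
  }
  if (qp) {
    s <- rowsum(res, pr$pi)
    grad[p + qt + as.integer(rownames(s))] <- s[, 1]
  }

  negH <- matrix(0, d, d)
  if (p) {
    negH[seq_len(p), seq_len(p)] <- crossprod(pr$X, pr$X * w)
  }
  if (qt) {
    wt <- rowsum(w, pr$ti)
    ks <- as.integer(rownames(wt))
    diag(negH)[p + ks] <- wt[, 1]
    if (p) {
      xt <- rowsum(pr$X * w, pr$ti)
      negH[seq_len(p), p + ks] <- t(xt)
      negH[p + ks, seq_len(p)] <- xt
    }
  }
  if (qp) {
    wp <- rowsum(w, pr$pi)
    ks <- as.integer(rownames(wp))
    diag(negH)[p + qt + ks] <- wp[, 1]
    if (p) {
      xp <- rowsum(pr$X * w, pr$pi)
      negH[seq_len(p), p + qt + ks] <- t(xp)
      negH[p + qt + ks, seq_len(p)] <- xp
    }
    if (qt) {
      key <- (pr$pi - 1L) * qt + pr$ti
      cp <- rowsum(w, key)
      kk <- as.integer(rownames(cp))
      kt <- (kk - 1L) %% qt + 1L
      kp <- (kk - 1L) %/% qt + 1L
      ii <- cbind(p + kt, p + qt + kp)
      negH[ii] <- negH[ii] + cp[, 1]
      negH[ii[, 2:1, drop = FALSE]] <- negH[ii[, 2:1, drop = FALSE]] + cp[, 1]
    }
  }
  negH <- negH - crossprod(G)
  list(loglik = loglik, grad = grad, negH = negH)
}

#' Cox partial log-likelihood on the gap-time axis
#'
#' Evaluates the partial log-likelihood of a proportional-hazards model with
#' linear predictor `eta` for recurrent-event gap-time data, with Efron or
#' Breslow handling of tied event times. Plain gap intervals enter the risk
#' set at time 0 and leave at their duration; counting-process segments with
#' delayed entry are supported through `start`.
#'
#' @param duration segment end times on the gap axis (the survival times).
#' @param event logical event indicators.
#' @param eta linear predictor values, `X beta + b_team + b_player` (+ any
#'   offset).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param start optional segment entry times (default 0).
#' @return the partial log-likelihood (a scalar).
#' @examples
#' # three intervals, one event: at eta = 0 the value is -log(risk set size)
#' partial_loglik(c(1, 2, 3), c(TRUE, FALSE, FALSE), rep(0, 3))  # -log(3)
#' @export
partial_loglik <- function(duration, event, eta,
                           ties = c("efron", "breslow"), start = NULL) {
  ties <- match.arg(ties)
  event <- as.logical(event)
  n <- length(duration)
  stopifnot(length(event) == n, length(eta) == n)
  X <- matrix(numeric(0), nrow = n, ncol = 0)
  pr <- prep_cox(duration, event, X, offset = eta, start = start)
  cox_derivs(pr, numeric(0), ties = ties, what = "loglik")$loglik
}

# ---- penalized Newton-Raphson at fixed variance components ----------------

# pen: length-d vector of penalty precisions (0 for fixed effects)
ppl_newton <- function(pr, pen, theta0 = NULL, ties = "efron",
                       reltol = 1e-8, maxit = 50L, derivs0 = NULL) {
  d <- pr$d
  theta <- theta0 %||% numeric(d)
  if (d == 0L) {
    ll <- cox_derivs(pr, theta, ties = ties, what = "loglik")$loglik
    return(list(theta = theta, ppl = ll, loglik = ll,
                derivs = list(loglik = ll, grad = numeric(0),
                              negH = matrix(0, 0, 0)),
                iterations = 0L, grad_norm = 0, trace = ll))
  }
  dv <- derivs0 %||% cox_derivs(pr, theta, ties = ties)
  ppl <- dv$loglik - 0.5 * sum(pen * theta^2)
  trace <- ppl
  iter <- 0L
  converged_step <- FALSE
  repeat {
    iter <- iter + 1L
    g <- dv$grad - pen * theta
    H <- dv$negH
    diag(H) <- diag(H) + pen
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(ch)) {
      ch <- tryCatch(chol(H + diag(1e-8 * (1 + abs(diag(H))), d)),
                     error = function(e) NULL)
      if (is.null(ch)) {
        stop_validation("penalized Hessian is singular (collinear design or separation)")
      }
    }
    step <- backsolve(ch, forwardsolve(t(ch), g))
    if (max(abs(step)) > 50) {
      stop_validation(paste0(
        "diverging Newton step (possible separation / unbounded coefficient); ",
        "largest step ", format(max(abs(step)))))
    }
    # step halving guarantees monotone increase of the penalized likelihood
    h <- 1
    repeat {
      theta_new <- theta + h * step
      ll_new <- cox_derivs(pr, theta_new, ties = ties,
                           what = "loglik")$loglik
      ppl_new <- ll_new - 0.5 * sum(pen * theta_new^2)
      if (ppl_new >= ppl - 1e-12 * (abs(ppl) + 1) || h < 1e-4) break
      h <- h / 2
    }
    converged_step <- abs(ppl_new - ppl) < reltol * (abs(ppl) + 1)
    theta <- theta_new
    ppl <- ppl_new
    trace <- c(trace, ppl)
    dv <- cox_derivs(pr, theta, ties = ties)
    if (converged_step || iter >= maxit) break
  }
  if (iter >= maxit && !converged_step) {
    abort(
      sprintf("inner Newton-Raphson did not converge in %d iterations", maxit),
      class = c("matchrisk_convergence_error", "matchrisk_error"),
      trace = trace
    )
  }
  g_final <- dv$grad - pen * theta
  list(theta = theta, ppl = ppl, loglik = dv$loglik, derivs = dv,
       iterations = iter, grad_norm = sqrt(sum(g_final^2)), trace = trace)
}

# Laplace-approximate integrated log-likelihood at fixed variances, evaluated
# at the joint (beta, b) mode of the penalized partial likelihood:
#   l_int = PPL(beta^, b^) - 1/2 log det( D Kbb D + I ),  D = diag(sigma_b)
# (the grouping of det(Sigma) with det(Kbb + Sigma^-1) keeps the expression
# finite and stable as variances approach zero, where it reduces to the Cox
# partial likelihood).
laplace_loglik <- function(fit_inner, pr, sigma_b) {
  q <- pr$qt + pr$qp
  if (!q) {
    return(fit_inner$loglik)
  }
  ib <- pr$p + seq_len(q)
  Kbb <- fit_inner$derivs$negH[ib, ib, drop = FALSE]
  M <- Kbb * tcrossprod(sigma_b)
  diag(M) <- diag(M) + 1
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    return(-Inf)
  }
  fit_inner$ppl - sum(log(diag(ch)))
}
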