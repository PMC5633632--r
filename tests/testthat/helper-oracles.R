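# Independent oracles used across the suite. The partial-likelihood oracle
# enumerates risk sets directly from the definition and never shares code
# with the package's engine.

oracle_pll <- function(stop, event, eta, ties = "efron", start = NULL) {
  start <- if (is.null(start)) rep(0, length(stop)) else start
  r <- exp(eta)
  ev_times <- sort(unique(stop[event]))
  ll <- 0
  for (t in ev_times) {
    D <- which(event & stop == t)
    R <- which(start < t & t <= stop)
    d <- length(D)
    Sr <- sum(r[R])
    Sd <- sum(r[D])
    ll <- ll + sum(eta[D])
    for (j in seq_len(d) - 1) {
      f <- if (ties == "efron") j / d else 0
      ll <- ll - log(Sr - f * Sd)
    }
  }
  ll
}

# a small random counting-process data set with a few forced ties; times
# live on an exact 0.1 grid (integer tenths) so tied values are bit-identical
# and the enumeration oracle needs no tie-tolerance logic
random_segments <- function(n = 12, seed = 1, p = 2, tied = TRUE) {
  set.seed(seed)
  start10 <- ifelse(runif(n) < 0.4, sample(0:30, n, replace = TRUE), 0L)
  stop10 <- start10 + sample(5:60, n, replace = TRUE)
  event <- runif(n) < 0.6
  if (tied && sum(event) >= 2) {
    ii <- which(event)[1:2]
    stop10[ii[2]] <- stop10[ii[1]]
    start10[ii[2]] <- min(start10[ii[2]], stop10[ii[2]] - 5L)
  }
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  list(start = start10 / 10, stop = stop10 / 10, event = event, X = X,
       eta = drop(X %*% rep(0.4, p)))
}

# quiet interval construction used everywhere
build_quiet <- function(bundle, ...) {
  build_intervals(bundle, quiet = TRUE, ...)
}

# small simulated cohort reused by several expensive-ish tests
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(
        sim_config(n_teams = 4, players_per_team = 12, n_seasons = 2),
        seed = 3
      )
    }
    cache
  }
})
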