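#' Magnitude-based inference for hazard ratios
#'
#' Classifies a hazard-ratio effect against smallest-worthwhile-effect
#' thresholds (default HR 0.90 for benefit, 1.11 for harm). The uncertainty
#' in the true effect is modelled as Normal on the log-HR scale with mean
#' `log(hr)` and SE back-calculated from the confidence interval,
#' `se = (log(ci_high) - log(ci_low)) / (2 z)` with `z` the two-sided
#' `conf` quantile (1.6449 at 90%). Then
#' \deqn{p_{beneficial} = \Phi\!\left(\frac{\log 0.90 - \log hr}{se}\right),
#'  \quad p_{harmful} = 1 - \Phi\!\left(\frac{\log 1.11 - \log hr}{se}\right)}
#' and the trivial probability is the remainder; the three unrounded
#' percentages sum to 100.
#'
#' Note the near-symmetry of the default thresholds on the log scale
#' (|log 0.90| = 0.10536 vs log 1.11 = 0.10436): a null effect gives almost,
#' but not exactly, equal beneficial and harmful probabilities. Some
#' published figure legends quote the harm threshold as HR 1.10; 1.11 is the
#' value used here (it is the reciprocal-style counterpart of 0.90 and
#' back-computation of published worked examples confirms it).
#'
#' `mbi_label()` applies the published decision rule: the effect is
#' *unclear* when the unrounded chances of benefit and harm both exceed 5%;
#' otherwise it takes the direction of the largest probability, qualified by
#' the probabilistic term of that probability on the scale <0.5% most
#' unlikely, 0.5–5% very unlikely, 5–25% unlikely, 25–75% possible(-ly),
#' 75–95% likely, 95–99.5% very likely, >99.5% most likely. Unrounded
#' percentages drive both the rule and the term; display rounding is half
#' away from zero.
#'
#' @param hr hazard-ratio point estimate(s).
#' @param ci_low,ci_high confidence-interval bounds (same length).
#' @param conf confidence level of the supplied interval (default 0.90).
#' @param benefit,harm hazard-ratio thresholds for beneficial and harmful
#'   effects.
#' @return [mbi_probs()]: tibble with unrounded percentage columns
#'   `p_beneficial`, `p_trivial`, `p_harmful`; [mbi_label()]: character
#'   vector of qualitative labels.
#' @examples
#' mbi_probs(1.28, 1.15, 1.41)         # ~ (0, 1, 99)
#' mbi_label(mbi_probs(1.28, 1.15, 1.41))  # "very likely harmful"
#' @export
mbi_probs <- function(hr, ci_low, ci_high, conf = 0.90, benefit = 0.90,
                      harm = 1.11) {
  if (any(ci_low <= 0 | hr <= 0 | ci_high <= 0)) {
    stop_validation("hazard ratios and CI bounds must be positive")
  }
  if (any(ci_low > hr | hr > ci_high)) {
    stop_validation("need ci_low <= hr <= ci_high")
  }
  if (benefit >= harm) {
    stop_validation("benefit threshold must be below harm threshold")
  }
  z <- qnorm(1 - (1 - conf) / 2)
  se <- (log(ci_high) - log(ci_low)) / (2 * z)
  mbi_probs_logscale(log(hr), se, benefit = benefit, harm = harm)
}

mbi_probs_logscale <- function(mu, se, benefit = 0.90, harm = 1.11) {
  pb <- ph <- numeric(length(mu))
  pointmass <- se <= 0
  if (any(pointmass)) {
    pb[pointmass] <- as.numeric(mu[pointmass] < log(benefit))
    ph[pointmass] <- as.numeric(mu[pointmass] > log(harm))
  }
  ok <- !pointmass
  pb[ok] <- pnorm((log(benefit) - mu[ok]) / se[ok])
  ph[ok] <- pnorm((log(harm) - mu[ok]) / se[ok], lower.tail = FALSE)
  tibble(p_beneficial = 100 * pb, p_trivial = 100 * (1 - pb - ph),
         p_harmful = 100 * ph)
}

mbi_terms <- data.frame(
  lo = c(0, 0.5, 5, 25, 75, 95, 99.5),
  term = c("most unlikely", "very unlikely", "unlikely", "possibly",
           "likely", "very likely", "most likely")
)

prob_term <- function(p) {
  # bands are lower-inclusive: [0, 0.5) most unlikely, [0.5, 5) very
  # unlikely, ..., [95, 99.5) very likely, [99.5, 100] most likely
  mbi_terms$term[findInterval(p, mbi_terms$lo)]
}

#' @rdname mbi_probs
#' @param probs a tibble from [mbi_probs()] (or any data frame with
#'   `p_beneficial`, `p_trivial`, `p_harmful` in percent, unrounded).
#' @param unclear_threshold the percentage both directional chances must
#'   exceed for an unclear call (default 5).
#' @export
mbi_label <- function(probs, unclear_threshold = 5) {
  pb <- probs$p_beneficial
  pt <- probs$p_trivial
  ph <- probs$p_harmful
  vapply(seq_along(pb), function(i) {
    if (pb[i] > unclear_threshold && ph[i] > unclear_threshold) {
      return("unclear")
    }
    ps <- c(beneficial = pb[i], trivial = pt[i], harmful = ph[i])
    k <- which.max(ps)
    paste(prob_term(ps[k]), names(ps)[k])
  }, character(1))
}

#' MBI classification straight from a fitted model term
#'
#' Applies the same normal-on-log-HR computation to a model coefficient and
#' its standard error, bypassing the loss of precision from rounding
#' confidence bounds for display.
#'
#' @param fit a `frailty_fit`.
#' @param term model term name.
#' @inheritParams mbi_probs
#' @return one-row tibble: term, hr, unrounded and rounded percentages,
#'   label, thresholds.
#' @export
mbi_from_fit <- function(fit, term, benefit = 0.90, harm = 1.11) {
  stopifnot(inherits(fit, "frailty_fit"))
  if (!term %in% names(fit$coefficients)) {
    stop_validation(sprintf("term '%s' is not in the model", term))
  }
  mu <- fit$coefficients[[term]]
  se <- fit$se[[term]]
  pr <- mbi_probs_logscale(mu, se, benefit = benefit, harm = harm)
  dplyr::bind_cols(tibble(term = term, hr = exp(mu)), mbi_round(pr))
}

mbi_round <- function(pr, benefit = 0.90, harm = 1.11) {
  dplyr::bind_cols(pr, tibble(
    beneficial = round_half_up(pr$p_beneficial),
    trivial = round_half_up(pr$p_trivial),
    harmful = round_half_up(pr$p_harmful),
    inference = mbi_label(pr),
    benefit_threshold = benefit, harm_threshold = harm
  ))
}

#' Batch MBI classification of an effects table
#'
#' Takes a table of effects with `hr`, `ci_low`, `ci_high` columns (e.g. the
#' output of [hr_per_2sd()] rows bound together, or an `fit.csv` written by
#' [run_pipeline()]) and appends the MBI percentages (unrounded and rounded)
#' and the qualitative inference for each row.
#'
#' @param effects data frame with columns `hr`, `ci_low`, `ci_high` and
#'   optionally `term`.
#' @inheritParams mbi_probs
#' @return `effects` with columns `p_beneficial`, `p_trivial`, `p_harmful`
#'   (unrounded), `beneficial`, `trivial`, `harmful` (rounded) and
#'   `inference` appended.
#' @examples
#' eff <- tibble::tibble(term = c("age", "prev"), hr = c(1.03, 1.28),
#'                       ci_low = c(0.98, 1.15), ci_high = c(1.09, 1.41))
#' mbi_table(eff)
#' @export
mbi_table <- function(effects, conf = 0.90, benefit = 0.90, harm = 1.11) {
  need <- c("hr", "ci_low", "ci_high")
  miss <- setdiff(need, names(effects))
  if (length(miss)) {
    stop_validation(sprintf("effects table lacks column(s): %s",
                            paste(miss, collapse = ", ")))
  }
  pr <- mbi_probs(effects$hr, effects$ci_low, effects$ci_high, conf = conf,
                  benefit = benefit, harm = harm)
  dplyr::bind_cols(as_tibble(effects), mbi_round(pr, benefit, harm))
}

#' Forest-style plot of MBI-classified effects
#'
#' @param effects output of [mbi_table()].
#' @param benefit,harm thresholds drawn as reference lines.
#' @export
plot_mbi <- function(effects, benefit = 0.90, harm = 1.11) {
  stopifnot(all(c("term", "hr", "ci_low", "ci_high") %in% names(effects)))
  ggplot2::ggplot(effects,
                  ggplot2::aes(x = .data$hr, y = .data$term)) +
    ggplot2::annotate("rect", ymin = -Inf, ymax = Inf,
                      xmin = benefit, xmax = harm, alpha = 0.15) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_continuous(trans = "log") +
    ggplot2::labs(x = "hazard ratio (log scale)", y = NULL)
}
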