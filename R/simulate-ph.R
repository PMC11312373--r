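#' Lean proportional-hazards group simulator
#'
#' Direct exponential event-time simulator for repeated-fit validation
#' studies (CI coverage, power, effect-modification designs), where the
#' full cohort generator would be needlessly heavy: participants are
#' assigned uniformly to exposure groups (and optionally to modifier
#' strata), event times are exponential with rate
#' `base_rate * exp(lp)`, and follow-up is administratively censored at
#' `censor_time`. The linear predictor is the group log hazard ratio,
#' optionally attenuated by the modifier stratum, plus the modifier main
#' effect. Uses the current RNG stream (seed with `set.seed()`).
#'
#' @param n Number of participants.
#' @param log_hrs Named log hazard ratios per exposure group (first name
#'   is the reference).
#' @param base_rate Baseline event rate per unit time.
#' @param censor_time Administrative censoring time.
#' @param modifier_log_hrs Optional named log hazard ratios for a modifier
#'   stratum main effect.
#' @param attenuation Optional named multipliers on the exposure log
#'   hazard ratio per modifier stratum.
#' @return Data frame with `time`, `event`, `group` (factor), and
#'   `modifier` when requested.
#' @export
simulate_ph_groups <- function(n, log_hrs, base_rate = 0.1,
                               censor_time = 10, modifier_log_hrs = NULL,
                               attenuation = NULL) {
  group <- factor(sample(names(log_hrs), n, replace = TRUE),
                  levels = names(log_hrs))
  lp <- unname(log_hrs[as.character(group)])
  out <- data.frame(group = group)
  if (!is.null(modifier_log_hrs)) {
    modifier <- factor(sample(names(modifier_log_hrs), n, replace = TRUE),
                       levels = names(modifier_log_hrs))
    att <- if (is.null(attenuation)) rep(1, n)
    else unname(attenuation[as.character(modifier)])
    lp <- lp * att + unname(modifier_log_hrs[as.character(modifier)])
    out$modifier <- modifier
  }
  t <- stats::rexp(n) / (base_rate * exp(lp))
  out$time <- pmin(t, censor_time)
  out$event <- as.integer(t <= censor_time)
  out
}

#' Lean proportional-hazards continuous-score simulator
#'
#' Companion to [simulate_ph_groups()] for dose-response validation:
#' exponential event times whose log hazard is an arbitrary function of a
#' continuous score, used e.g. to verify that the spline nonlinearity test
#' keeps its size under a linear truth and detects a J-shaped truth.
#'
#' @param score Numeric vector of exposure scores (length defines n).
#' @param log_hazard Function mapping the score to the log relative
#'   hazard.
#' @param base_rate Baseline event rate per unit time.
#' @param censor_time Administrative censoring time.
#' @return Data frame with `score`, `time`, `event`.
#' @export
simulate_ph_score <- function(score, log_hazard, base_rate = 0.1,
                              censor_time = 10) {
  lp <- log_hazard(score)
  t <- stats::rexp(length(score)) / (base_rate * exp(lp))
  data.frame(score = score, time = pmin(t, censor_time),
             event = as.integer(t <= censor_time))
}
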