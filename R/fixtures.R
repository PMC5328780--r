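#' Synthetic three-leg beta traces
#'
#' Generates square-wave-like per-leg beta time series with a given period,
#' elevation duty cycle and inter-leg phase lags, so the gait-analysis stage
#' can be exercised independently of the dynamical model.  Lags are
#' fractions of the period at which each leg lifts off, in the order FL, ML,
#' HL; `c(0, 0.5, 0)` is a tripod template and `c(2/3, 1/3, 0)` a tetrapod
#' one.
#'
#' @param period_ms Step period (ms).
#' @param duty Fraction of the period the leg is lifted, in (0, 1).
#' @param lags Numeric length-3 lift-off lags for FL, ML, HL.
#' @param n_cycles Number of cycles.
#' @param noise Gaussian noise standard deviation (degrees).
#' @param seed RNG seed fixing the noise.
#' @param dt Sample interval (ms).
#' @param beta_low,beta_high Ground / lifted beta levels (degrees).
#' @return Data frame `t_ms`, `beta.FL`, `beta.ML`, `beta.HL`.
#' @export
make_fixture <- function(period_ms, duty, lags, n_cycles = 10, noise = 0,
                         seed = 1, dt = 1, beta_low = 30, beta_high = 60) {
  stopifnot(duty > 0, duty < 1, length(lags) == 3)
  t <- seq(0, n_cycles * period_ms, by = dt)
  out <- data.frame(t_ms = t)
  set.seed(seed)
  for (i in seq_along(LEGS)) {
    ph <- ((t / period_ms) - lags[i]) %% 1
    beta <- ifelse(ph < duty, beta_high, beta_low)
    if (noise > 0) beta <- beta + stats::rnorm(length(t), 0, noise)
    out[[paste0("beta.", LEGS[i])]] <- beta
  }
  out
}

#' Gait summary of a fixture
#'
#' Convenience wrapper running event detection and pattern classification on
#' a [make_fixture()] data frame.
#'
#' @param fx Fixture data frame.
#' @param ... Passed to [classify_pattern()].
#' @inheritParams detect_events
#' @return An `sw_gait` classification.
#' @export
classify_fixture <- function(fx, ground_threshold = 33, hysteresis = 1, ...) {
  events <- lapply(setNames(LEGS, LEGS), function(leg)
    detect_events(fx$t_ms, fx[[paste0("beta.", leg)]], ground_threshold,
                  hysteresis))
  classify_pattern(events, ...)
}
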