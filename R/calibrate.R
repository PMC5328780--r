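#' Stepping period of the control model
#'
#' Runs the unperturbed model in one mode and reports the mean interval
#' between successive hind-leg lift-offs.
#'
#' @param model An `sw_model`.
#' @param mode Coordination mode.
#' @param t_total Run length (ms).
#' @param settle Discarded transient (ms).
#' @param dt Integration step (ms).
#' @return List with `period` (ms), `cv` and `n` lift-offs.
#' @export
measure_period <- function(model, mode, t_total = 20000, settle = 5000,
                           dt = 0.1) {
  traj <- simulate_scenario(model, t_span = t_total, mode = mode, dt = dt)
  ev <- detect_events(traj$kin$t_ms, traj$kin$beta.HL)
  lo <- ev$t[ev$kind == "liftoff" & ev$t >= settle]
  if (length(lo) < 3) return(list(period = NA_real_, cv = NA_real_,
                                  n = length(lo)))
  d <- diff(lo)
  list(period = mean(d), cv = stats::sd(d) / mean(d), n = length(lo))
}

#' Calibrate the control periods by scaling the LD drives
#'
#' The stepping period falls monotonically with the central drive to the
#' levator-depressor CPGs over the model's operating range.  For each mode,
#' a bisection on a common scale factor applied to all six LD drives (three
#' legs, levator and depressor) adjusts the period to the target within the
#' requested tolerance.  The search is deterministic.
#'
#' @param config An `sw_config` to calibrate.
#' @param targets Named list of target periods (ms) per mode, e.g.
#'   `list(tetrapod = 1180, tripod = 615)`.
#' @param tol Relative tolerance on the period.
#' @param scale_bounds Search interval for the drive scale factor.
#' @param max_iter Bisection iterations per mode.
#' @param t_total,settle Passed to [measure_period()].
#' @return List with `config` (calibrated) and `report` (data frame per
#'   mode: achieved period, scale, met).
#' @export
calibrate <- function(config = default_config(),
                      targets = list(tetrapod = 1180, tripod = 615),
                      tol = 0.05, scale_bounds = c(0.5, 2), max_iter = 10,
                      t_total = 20000, settle = 5000) {
  report <- NULL
  for (mode in names(targets)) {
    tgt <- targets[[mode]]
    eval_scale <- function(u) {
      cfg2 <- scale_ld_drives(config, mode, u)
      measure_period(build_model(cfg2), mode, t_total, settle)$period
    }
    lo <- scale_bounds[1]; hi <- scale_bounds[2]
    p_lo <- eval_scale(lo); p_hi <- eval_scale(hi)
    # period decreases with drive: p_lo is the long-period end
    best <- c(scale = 1, period = eval_scale(1))
    if (is.finite(best["period"]) &&
        abs(best["period"] - tgt) / tgt <= tol) {
      report <- rbind(report, data.frame(mode = mode, scale = 1,
                                         period = best[["period"]],
                                         target = tgt, met = TRUE))
      next
    }
    met <- FALSE
    for (i in seq_len(max_iter)) {
      mid <- sqrt(lo * hi)
      p_mid <- eval_scale(mid)
      if (!is.finite(p_mid)) { hi <- mid; next }
      if (abs(p_mid - tgt) < abs(best["period"] - tgt) ||
          !is.finite(best["period"]))
        best <- c(scale = mid, period = p_mid)
      if (abs(p_mid - tgt) / tgt <= tol) { met <- TRUE; break }
      if (p_mid > tgt) lo <- mid else hi <- mid
    }
    config <- scale_ld_drives(config, mode, best[["scale"]])
    report <- rbind(report, data.frame(mode = mode, scale = best[["scale"]],
                                       period = best[["period"]],
                                       target = tgt, met = met ||
                                         abs(best[["period"]] - tgt) / tgt <= tol))
  }
  list(config = config, report = report)
}

# multiply the six LD drives of one mode by u
scale_ld_drives <- function(config, mode, u) {
  for (l in 0:2) for (j in 3:4) {
    k <- paste0("g_app", 6 * l + j)
    config$modes[[mode]]$g_app[[k]] <- config$modes[[mode]]$g_app[[k]] * u
  }
  config
}
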