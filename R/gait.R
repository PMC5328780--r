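#' Detect lift-off and touch-down events from a beta trace
#'
#' Lift-off is an upward crossing of beta through the ground-contact
#' threshold, touch-down a downward crossing; a symmetric hysteresis band
#' debounces ripple around the threshold, so events of the same kind never
#' repeat without the opposite crossing in between.
#'
#' @param t Sample times (ms), uniformly spaced.
#' @param beta Beta angle trace (degrees).
#' @param ground_threshold Threshold (degrees).
#' @param hysteresis Half-width of the debounce band (degrees).
#' @return Data frame with columns `kind` (`"liftoff"`/`"touchdown"`) and
#'   `t` (ms), ordered in time.
#' @export
detect_events <- function(t, beta, ground_threshold = 33, hysteresis = 1) {
  if (length(t) != length(beta)) stop("t and beta differ in length")
  if (length(t) > 2) {
    dts <- diff(t)
    if (max(dts) - min(dts) > 1e-6 * stats::median(dts))
      stop("trace is not uniformly sampled", call. = FALSE)
  }
  up <- ground_threshold + hysteresis
  dn <- ground_threshold - hysteresis
  lifted <- beta[1] > ground_threshold
  kinds <- character(0); times <- numeric(0)
  # vectorised state machine over threshold-band exits
  above <- beta >= up; below <- beta <= dn
  idx <- which(above | below)
  state <- lifted
  for (i in idx) {
    if (!state && above[i]) {
      state <- TRUE; kinds <- c(kinds, "liftoff"); times <- c(times, t[i])
    } else if (state && below[i]) {
      state <- FALSE; kinds <- c(kinds, "touchdown"); times <- c(times, t[i])
    }
  }
  data.frame(kind = kinds, t = times)
}

#' Step periods of one leg
#'
#' @param events Event data frame from [detect_events()].
#' @return List with `period` (mean lift-off interval, ms), `cv`
#'   (coefficient of variation) and `n` (number of lift-offs).
#' @export
leg_periods <- function(events) {
  lo <- events$t[events$kind == "liftoff"]
  if (length(lo) < 3) return(list(period = NA_real_, cv = NA_real_,
                                  n = length(lo)))
  d <- diff(lo)
  list(period = mean(d), cv = stats::sd(d) / mean(d), n = length(lo))
}

# circular mean of phases in [0, 1)
circ_mean <- function(ph) {
  z <- mean(exp(2i * pi * ph))
  (Arg(z) / (2 * pi)) %% 1
}

# phase of leg A's lift-offs relative to leg B's lift-off cycle
pair_phase <- function(lo_a, lo_b) {
  if (length(lo_b) < 2 || !length(lo_a)) return(NA_real_)
  Tb <- mean(diff(lo_b))
  ph <- vapply(lo_b[-length(lo_b)], function(tb) {
    nxt <- lo_a[lo_a >= tb]
    if (!length(nxt)) return(NA_real_)
    ((nxt[1] - tb) / Tb) %% 1
  }, 0)
  ph <- ph[!is.na(ph)]
  if (!length(ph)) return(NA_real_)
  circ_mean(ph)
}

# distance on the unit circle of phases
circ_dist <- function(a, b) {
  d <- abs((a - b) %% 1)
  pmin(d, 1 - d)
}

#' Classify the coordination pattern from per-leg step events
#'
#' Tripod: front and hind leg lift off in phase, the middle leg in
#' anti-phase with them.  Tetrapod: lift-off order hind, middle, front leg
#' with successive lags of about one third of a period.  A leg with no
#' events within two reference periods of the end of the analysis window
#' counts as stopped and is excluded from the phase computation.  Anything
#' else is an unusual pattern.
#'
#' @param events Named list (`FL`, `ML`, `HL`) of event data frames.
#' @param tol Phase tolerance (fraction of a period).
#' @param min_cycles Minimum number of complete cycles required per
#'   non-stopped leg; fewer raise an insufficient-data error.
#' @param window Optional `c(t0, t1)` restricting the analysis.
#' @return List of class `sw_gait` with per-leg `period`, `cv`, `n`,
#'   pairwise `phases`, `pattern` (`"tripod"`, `"tetrapod"`, `"unusual"` or
#'   `"stopped"`) and `stopped` (character vector of stopped legs).
#' @export
classify_pattern <- function(events, tol = 0.1, min_cycles = 5,
                             window = NULL) {
  stopifnot(all(LEGS %in% names(events)))
  if (!is.null(window))
    events <- lapply(events, function(e) e[e$t >= window[1] & e$t <= window[2], ])
  lo <- lapply(events[LEGS], function(e) e$t[e$kind == "liftoff"])
  pers <- lapply(events[LEGS], leg_periods)
  t_end <- max(unlist(lapply(events, function(e) e$t)), -Inf)
  T_ref <- stats::median(unlist(lapply(pers, `[[`, "period")), na.rm = TRUE)
  stopped <- vapply(LEGS, function(l) {
    if (!length(lo[[l]])) return(TRUE)
    if (is.na(T_ref)) return(length(lo[[l]]) < 2)
    max(lo[[l]]) < t_end - 2 * T_ref || length(lo[[l]]) < 2
  }, TRUE)
  active <- LEGS[!stopped]
  for (l in active)
    if (pers[[l]]$n - 1 < min_cycles)
      stop("insufficient data: leg ", l, " has only ", pers[[l]]$n - 1,
           " complete cycles (need ", min_cycles, ")", call. = FALSE)
  phases <- c(FL_HL = pair_phase(lo$FL, lo$HL),
              ML_HL = pair_phase(lo$ML, lo$HL),
              FL_ML = pair_phase(lo$FL, lo$ML))
  pattern <- if (any(stopped)) "stopped" else if (
    circ_dist(phases["FL_HL"], 0) < tol &&
    circ_dist(phases["ML_HL"], 0.5) < tol) "tripod" else if (
    circ_dist(phases["ML_HL"], 1 / 3) < tol &&
    circ_dist(phases["FL_ML"], 1 / 3) < tol) "tetrapod" else "unusual"
  structure(list(periods = pers, phases = phases, pattern = pattern,
                 stopped = LEGS[stopped]),
            class = "sw_gait")
}

#' @export
print.sw_gait <- function(x, ...) {
  cat("pattern:", x$pattern)
  if (length(x$stopped)) cat("  (stopped:", paste(x$stopped, collapse = ", "), ")")
  cat("\nphases (FL|HL, ML|HL, FL|ML):",
      paste(sprintf("%.3f", x$phases), collapse = ", "), "\n")
  for (l in LEGS)
    if (!is.na(x$periods[[l]]$period))
      cat(sprintf("  %s period %.0f ms (cv %.3f, n=%d)\n", l,
                  x$periods[[l]]$period, x$periods[[l]]$cv, x$periods[[l]]$n))
  invisible(x)
}

#' Classify the steady posture of a stopped leg
#'
#' The two canonical postures are the lifted, protracted and extended leg
#' (beta near 60, alpha near 28, gamma near 45) and its complement on the
#' ground, retracted and flexed (beta near 30, alpha near 128, gamma near
#' 110).  The hind leg, whose tibia works in anti-phase, can instead stop on
#' the ground retracted and stretched (gamma near 45) or lifted, protracted
#' and flexed; these are reported with their angles.
#'
#' @param angles Data frame with columns `alpha`, `beta`, `gamma` covering
#'   the steady tail of a simulation.
#' @param tol_deg Tolerance (degrees) for "near" a nominal angle.
#' @param steady_tol Maximal allowed range (degrees) of each angle over the
#'   slice; a larger range raises a non-steady error.
#' @return List with `label`, `alpha`, `beta`, `gamma`.
#' @export
classify_posture <- function(angles, tol_deg = 5, steady_tol = 1) {
  rng <- vapply(angles[c("alpha", "beta", "gamma")],
                function(v) diff(range(v)), 0)
  if (any(rng > steady_tol))
    stop("angle slice is not steady (range ",
         sprintf("%.2f", max(rng)), " deg); extend the simulation",
         call. = FALSE)
  m <- vapply(angles[c("alpha", "beta", "gamma")], mean, 0)
  near <- function(x, v) abs(x - v) <= tol_deg
  label <- if (near(m["beta"], 60) && near(m["alpha"], 28) && near(m["gamma"], 45))
    "lifted_protracted_extended"
  else if (near(m["beta"], 30) && near(m["alpha"], 128) && near(m["gamma"], 110))
    "grounded_retracted_flexed"
  else if (near(m["beta"], 30) && near(m["alpha"], 128) && near(m["gamma"], 45))
    "grounded_retracted_stretched"
  else if (near(m["beta"], 60) && near(m["alpha"], 28) && near(m["gamma"], 110))
    "lifted_protracted_flexed"
  else sprintf("other(%.0f,%.0f,%.0f)", m["alpha"], m["beta"], m["gamma"])
  list(label = label, alpha = unname(m["alpha"]), beta = unname(m["beta"]),
       gamma = unname(m["gamma"]))
}

#' Gait summary of a trajectory window
#'
#' Detects step events per leg, estimates periods and phase lags, labels the
#' coordination pattern, and classifies the posture of every stopped leg.
#'
#' @param traj An `sw_trajectory`.
#' @param window `c(t0, t1)` (ms); default the final 7.5 seconds
#'   (at least five slow-mode cycles).
#' @param ground_threshold,hysteresis Passed to [detect_events()].
#' @param tol,min_cycles Passed to [classify_pattern()].
#' @return List of class `sw_gait_summary`.
#' @export
summarize_gait <- function(traj, window = NULL, ground_threshold = 33,
                           hysteresis = 1, tol = 0.1, min_cycles = 5) {
  tmax <- max(traj$kin$t_ms)
  if (is.null(window)) window <- c(max(0, tmax - 7500), tmax)
  keep <- traj$kin$t_ms >= window[1] & traj$kin$t_ms <= window[2]
  events <- lapply(setNames(LEGS, LEGS), function(leg)
    detect_events(traj$kin$t_ms[keep], traj$kin[[paste0("beta.", leg)]][keep],
                  ground_threshold, hysteresis))
  gait <- classify_pattern(events, tol = tol, min_cycles = min_cycles)
  postures <- list()
  for (leg in gait$stopped) {
    sl <- data.frame(alpha = traj$kin[[paste0("alpha.", leg)]][keep],
                     beta = traj$kin[[paste0("beta.", leg)]][keep],
                     gamma = traj$kin[[paste0("gamma.", leg)]][keep])
    n <- nrow(sl)
    tail_n <- min(n, max(2000 %/% max(traj$sample_dt, 1), 2))
    postures[[leg]] <- tryCatch(
      classify_posture(sl[(n - tail_n + 1):n, ]),
      error = function(e) list(label = "non_steady", alpha = NA, beta = NA,
                               gamma = NA))
  }
  structure(c(unclass(gait), list(postures = postures, events = events,
                                  window = window)),
            class = c("sw_gait_summary", "sw_gait"))
}

#' Per-leg stance intervals (podogram)
#'
#' @param events Named list of event data frames (per leg).
#' @param window `c(t0, t1)` bounds for open intervals.
#' @return Data frame `leg`, `t_on`, `t_off` of ground-contact intervals.
#' @export
stance_intervals <- function(events, window) {
  out <- NULL
  for (leg in names(events)) {
    e <- events[[leg]]
    bounds <- c(window[1], e$t, window[2])
    kinds <- c(NA, e$kind, NA)
    # stance runs from a touchdown (or window start) to the next liftoff
    state_start <- window[1]
    in_stance <- if (nrow(e)) e$kind[1] == "liftoff" else NA
    if (is.na(in_stance)) next
    for (i in seq_len(nrow(e))) {
      if (e$kind[i] == "liftoff") {
        out <- rbind(out, data.frame(leg = leg, t_on = state_start,
                                     t_off = e$t[i]))
      } else state_start <- e$t[i]
    }
    if (nrow(e) && e$kind[nrow(e)] == "touchdown")
      out <- rbind(out, data.frame(leg = leg, t_on = state_start,
                                   t_off = window[2]))
  }
  out
}

#' Write step events as JSON
#'
#' @param events Named list of per-leg event data frames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events_json <- function(events, path) {
  flat <- do.call(rbind, lapply(names(events), function(leg) {
    e <- events[[leg]]
    if (!nrow(e)) return(NULL)
    data.frame(leg = leg, kind = e$kind, t_ms = e$t)
  }))
  jsonlite::write_json(flat, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
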