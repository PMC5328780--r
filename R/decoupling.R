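#' Decoupling commands
#'
#' Constructors for the three mechanisms that decouple one leg from the
#' coordination chain, plus a coordination-mode switch.  Each command is a
#' scheduled, reversible set of conductance rewrites.
#'
#' `decouple_intersegmental()` perturbs the intersegmental synapse onto the
#' leg's levator CPG neuron: `"make_excitatory"` fixes the synapse at a
#' positive conductance with reversal potential zero; `"block"` sets its
#' conductance to zero.  It is undefined for the hind leg, which has no
#' intersegmental synapse on its LD CPG.
#'
#' `decouple_cpg_drive()` rewrites the central drives of the leg's LD CPG
#' pair.  Variants: `"lift"` (tonic excitation of the levator neuron, tonic
#' inhibition of the depressor), `"ground"` (the reverse), `"zero"` (both
#' drives removed), or `"custom"` with explicit `overrides`.  Strong
#' excitation/inhibition is `strong_factor` times the baseline drive.  The
#' outcome of this mechanism can depend on the phase of the stepping period
#' at which the command arrives.
#'
#' `decouple_premotor()` rewrites the tonic inhibition `g_d` of the leg's
#' two LD premotor interneurons: `"lift"` fully disinhibits the
#' depressor-path IN (suppressing the depressor MN) and inhibits the
#' levator-path IN (freeing the levator MN); `"ground"` is the mirror
#' image.  This mechanism acts downstream of the CPG and is effective
#' regardless of the phase of the stepping period.
#'
#' @param leg `"FL"`, `"ML"` or `"HL"`.
#' @param variant Mechanism-specific variant, see above.
#' @param onset Onset time (ms), or `NULL` with `anchor`.
#' @param anchor Only `"HL_liftoff"`: anchor the onset to the first hind-leg
#'   lift-off after settling, plus `anchor_offset_ms`.
#' @param anchor_offset_ms Offset (ms) added to the anchor event time.
#' @param offset_time Optional removal time (ms); baseline values are
#'   restored then.
#' @param g Conductance for `"make_excitatory"` (defaults to the mode's
#'   baseline maximal conductance).
#' @param fixed For `"make_excitatory"`: if `TRUE` the synapse is pinned at
#'   the constant conductance `g`; if `FALSE` only the reversal potential
#'   flips and the strength stays weighted by the posterior beta mapping.
#' @param overrides For `variant = "custom"`: named list keyed by drive
#'   symbols (e.g. `g_app3`), each value a list with optional `exc` and
#'   `inh` conductances.
#' @return An `sw_command`.
#' @name decoupling
NULL

new_command <- function(mechanism, leg, variant, onset, anchor,
                        anchor_offset_ms, offset_time, extra = list()) {
  if (!is.null(onset) && !is.numeric(onset))
    stop("onset must be a time in ms or NULL (with an anchor)", call. = FALSE)
  structure(c(list(mechanism = mechanism, leg = leg, variant = variant,
                   onset_ms = onset, anchor = anchor,
                   anchor_offset_ms = anchor_offset_ms,
                   offset_ms = offset_time,
                   label = paste(mechanism, leg, variant, sep = ":")),
              extra),
            class = "sw_command")
}

#' @rdname decoupling
#' @export
decouple_intersegmental <- function(leg, variant = c("make_excitatory", "block"),
                                    onset = NULL, anchor = "HL_liftoff",
                                    anchor_offset_ms = 0, offset_time = NULL,
                                    g = NULL, fixed = TRUE) {
  variant <- match.arg(variant)
  if (!leg %in% c("FL", "ML"))
    stop("invalid command: there are no intersegmental coordinating ",
         "synapses on the LD CPG of the hind leg", call. = FALSE)
  new_command("intersegmental_synapse", leg, variant, onset, anchor,
              anchor_offset_ms, offset_time, list(g = g, fixed = fixed))
}

#' @rdname decoupling
#' @param strong_factor Multiple of the baseline drive used for "strong"
#'   excitation/inhibition; default from the model configuration.
#' @export
decouple_cpg_drive <- function(leg, variant = c("lift", "ground", "zero", "custom"),
                               onset = NULL, anchor = "HL_liftoff",
                               anchor_offset_ms = 0, offset_time = NULL,
                               overrides = NULL, strong_factor = NULL) {
  variant <- match.arg(variant)
  leg <- match.arg(leg, LEGS)
  if (variant == "custom" && is.null(overrides))
    stop("custom drive decoupling needs explicit overrides", call. = FALSE)
  new_command("cpg_drive", leg, variant, onset, anchor, anchor_offset_ms,
              offset_time, list(overrides = overrides,
                                strong_factor = strong_factor))
}

#' @rdname decoupling
#' @export
decouple_premotor <- function(leg, variant = c("lift", "ground"),
                              onset = NULL, anchor = "HL_liftoff",
                              anchor_offset_ms = 0, offset_time = NULL) {
  variant <- match.arg(variant)
  leg <- match.arg(leg, LEGS)
  new_command("premotor_in", leg, variant, onset, anchor, anchor_offset_ms,
              offset_time)
}

#' @rdname decoupling
#' @param mode Mode to switch to.
#' @export
mode_switch <- function(mode, onset) {
  stopifnot(is.numeric(onset))
  structure(list(mechanism = "mode_switch", mode = mode, onset_ms = onset,
                 label = paste0("mode_switch:", mode)),
            class = "sw_command")
}

# translate one command into engine parameter overrides (named vector)
command_overrides <- function(model, cm, p_base) {
  leg <- cm$leg
  cfg <- model$config
  key <- function(stem, j) paste0(stem, j, ".", leg)
  if (cm$mechanism == "intersegmental_synapse") {
    if (!leg %in% c("FL", "ML"))
      stop("invalid command: no intersegmental synapse targets the hind leg",
           call. = FALSE)
    if (cm$variant == "make_excitatory") {
      g <- cm$g %||% unname(p_base[paste0("is_g.", leg)])
      # fixed: a constant positive conductance with reversal potential zero;
      # otherwise only the reversal potential flips and the strength stays
      # governed by the posterior beta mapping
      if (isTRUE(cm$fixed))
        return(setNames(c(1, g, 0),
                        paste0(c("is_fix.", "is_g.", "is_E."), leg)))
      return(setNames(c(g, 0), paste0(c("is_g.", "is_E."), leg)))
    }
    return(setNames(c(1, 0), paste0(c("is_fix.", "is_g."), leg)))
  }
  if (cm$mechanism == "cpg_drive") {
    f <- cm$strong_factor %||% cfg$decoupling$strong_factor
    # "strong" is f times a fixed reference drive, so that the same command
    # applies the same physical conductances in either starting mode
    b_ref <- cfg$decoupling$ref_drive %||% 0.4
    ov <- switch(cm$variant,
      lift = setNames(c(f * b_ref, 0, 0, f * b_ref),
                      c(key("gappE", 3), key("gappI", 3),
                        key("gappE", 4), key("gappI", 4))),
      ground = setNames(c(f * b_ref, 0, 0, f * b_ref),
                        c(key("gappE", 4), key("gappI", 4),
                          key("gappE", 3), key("gappI", 3))),
      zero = setNames(c(0, 0, 0, 0),
                      c(key("gappE", 3), key("gappI", 3),
                        key("gappE", 4), key("gappI", 4))),
      custom = {
        l <- match(leg, LEGS) - 1
        out <- c()
        for (nm in names(cm$overrides)) {
          j <- suppressWarnings(as.integer(sub("g_app", "", nm))) - 6 * l
          if (is.na(j) || j < 1 || j > 6)
            stop("unknown drive key '", nm, "' for leg ", leg, call. = FALSE)
          spec <- cm$overrides[[nm]]
          if (!is.null(spec$exc)) out[key("gappE", j)] <- spec$exc
          if (!is.null(spec$inh)) out[key("gappI", j)] <- spec$inh
        }
        out
      })
    return(ov)
  }
  if (cm$mechanism == "premotor_in") {
    gs <- cfg$decoupling$gd_strong
    # engine premotor-IN order: index 3 = levator path, 4 = depressor path
    if (cm$variant == "lift")
      return(setNames(c(0, gs), c(key("gd", 4), key("gd", 3))))
    return(setNames(c(0, gs), c(key("gd", 3), key("gd", 4))))
  }
  stop("unknown mechanism '", cm$mechanism, "'", call. = FALSE)
}

# outcome of a decoupling run for one leg over the final window:
# "stepping", "lifted", "grounded" or "other"
decoupling_outcome <- function(traj, leg, window = NULL) {
  tmax <- max(traj$kin$t_ms)
  if (is.null(window)) window <- c(tmax - 5000, tmax)
  keep <- traj$kin$t_ms >= window[1] & traj$kin$t_ms <= window[2]
  beta <- traj$kin[[paste0("beta.", leg)]][keep]
  ev <- detect_events(traj$kin$t_ms[keep], beta)
  if (sum(ev$kind == "liftoff") >= 2) return("stepping")
  rng <- diff(range(beta))
  if (rng > 5) return("other")
  if (mean(beta) >= 50) "lifted" else if (mean(beta) <= 40) "grounded" else "other"
}

#' Sweep the onset phase of a decoupling command
#'
#' Applies the same command at `n_phases` equally spaced onsets across one
#' stepping period, anchored at a hind-leg lift-off of the unperturbed
#' rhythm, classifies each outcome from the final seconds of the run, and
#' summarises the contiguous window of onsets in which the command succeeds.
#'
#' @param model An `sw_model`.
#' @param command An `sw_command` template (its onset is ignored).
#' @param n_phases Number of onsets (at least 16).
#' @param mode Starting coordination mode.
#' @param t_total Length of each run (ms).
#' @param settle Settling time before the anchor lift-off (ms).
#' @param final_window Length of the classification window at the end of
#'   each run (ms).
#' @param success Outcome label counting as success; defaults to `"lifted"`
#'   for lift-type variants, `"grounded"` for ground-type ones.
#' @return List with `results` (one row per onset: `onset_ms`, `phase`,
#'   `outcome`), `period`, `anchor_ms`, `success_window_ms` (length of the
#'   longest contiguous success arc), `window_start_phase`,
#'   `success_fraction`.
#' @export
sweep_command_phase <- function(model, command, n_phases = 24,
                                mode = "tetrapod", t_total = 20000,
                                settle = 5000, final_window = 5000,
                                success = NULL) {
  if (n_phases < 16) stop("n_phases must be at least 16", call. = FALSE)
  ref <- simulate_scenario(model, t_span = t_total, mode = mode)
  ev <- detect_events(ref$kin$t_ms, ref$kin$beta.HL)
  lo <- ev$t[ev$kind == "liftoff" & ev$t >= settle]
  if (length(lo) < 3) stop("reference run has too few hind-leg lift-offs",
                           call. = FALSE)
  period <- mean(diff(lo))
  anchor <- lo[1]
  if (is.null(success))
    success <- switch(command$variant, lift = "lifted",
                      ground = "grounded", "lifted")
  onsets <- anchor + (seq_len(n_phases) - 1) / n_phases * period
  outcomes <- character(n_phases)
  for (i in seq_len(n_phases)) {
    cm <- command; cm$onset_ms <- onsets[i]
    traj <- simulate_scenario(model, t_span = t_total, mode = mode,
                              commands = list(cm))
    outcomes[i] <- decoupling_outcome(traj, command$leg,
                                      c(t_total - final_window, t_total))
  }
  res <- data.frame(onset_ms = onsets,
                    phase = (onsets - anchor) / period, outcome = outcomes)
  ok <- outcomes == success
  run <- longest_circular_run(ok)
  list(results = res, period = period, anchor_ms = anchor,
       success_window_ms = run$length * period / n_phases,
       window_start_phase = if (run$length) (run$start - 1) / n_phases else NA,
       success_fraction = mean(ok))
}

# longest run of TRUE on a circular vector; returns start index and length
longest_circular_run <- function(ok) {
  n <- length(ok)
  if (all(ok)) return(list(start = 1L, length = n))
  if (!any(ok)) return(list(start = NA_integer_, length = 0L))
  okk <- c(ok, ok)
  best_len <- 0L; best_start <- NA_integer_; cur <- 0L
  for (i in seq_len(2 * n)) {
    if (okk[i]) {
      cur <- cur + 1L
      if (cur > best_len && i - cur + 1L <= n) {
        best_len <- min(cur, n)
        best_start <- i - cur + 1L
      }
    } else cur <- 0L
  }
  list(start = best_start, length = best_len)
}
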