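#' Build the three-leg model
#'
#' Assembles the front (pro), middle (meso) and hind (meta) leg networks and
#' the two intersegmental inhibitory pathways: the middle leg's beta angle
#' sets the strength of the synapse (`g_inh3`) onto the front-leg levator
#' CPG neuron C3, and the hind leg's beta that of the synapse (`g_inh9`)
#' onto the middle-leg levator neuron C9.  The hind-leg LD CPG receives no
#' intersegmental input and is the source of the rhythm; rhythmic activity
#' propagates posterior to anterior.
#'
#' @param config An `sw_config`; see [default_config()] and
#'   [baseline_config()].
#' @return An object of class `sw_model`.
#' @export
build_model <- function(config = baseline_config()) {
  validate_config(config)
  legs <- lapply(c("pro", "meso", "meta"), build_leg, config = config)
  names(legs) <- LEGS
  model <- structure(
    list(config = config, legs = legs,
         chain = data.frame(source = c("ML", "HL"), target = c("FL", "ML"),
                            synapse = c("g_inh3", "g_inh9"),
                            onto = c("C3", "C9"))),
    class = "sw_model")
  model
}

#' @export
print.sw_model <- function(x, ...) {
  cat("Three-leg stick insect model\n")
  cat("  modes:", paste(names(x$config$modes), collapse = ", "), "\n")
  cat("  intersegmental chain: HL -> ML -> FL (inhibition of the anterior",
      "levator CPG neuron)\n")
  invisible(x)
}

#' Topology signature of a model
#'
#' A canonical string over all units and synapses of the three legs plus the
#' intersegmental chain.  Mode switches change drives and mappings only, so
#' the signature is invariant under them.
#'
#' @param model An `sw_model`.
#' @return A character scalar.
#' @export
topology_hash <- function(model) {
  rows <- unlist(lapply(model$legs, function(lg)
    paste(lg$synapses$pre, lg$synapses$post, lg$synapses$type, sep = ">")))
  rows <- c(rows, paste(model$chain$source, model$chain$target,
                        model$chain$onto, sep = ">"))
  paste(sort(rows), collapse = ";")
}

#' Instantaneous strength of an intersegmental synapse
#'
#' The synaptic strength is a memoryless function of the posterior leg's
#' beta angle: a steep sigmoid that is close to zero when the posterior leg
#' is on the ground (beta near 30) and close to `g_max` when it is lifted.
#' The optional velocity gate (`dgate`) additionally requires the posterior
#' beta to be rising.
#'
#' @param beta_posterior Beta angle of the next posterior leg (degrees).
#' @param mode Mode name, or a list with `g_inh`, `theta`, `slope`, `dgate`.
#' @param model An `sw_model` (used when `mode` is a name).
#' @param leg Anterior target leg, `"FL"` or `"ML"`.
#' @param dbeta_posterior Angular velocity of the posterior beta (deg/ms),
#'   used only when the velocity gate is on.
#' @return Conductance in \[0, g_max\].
#' @export
intersegmental_strength <- function(beta_posterior, mode = "tetrapod",
                                    model = build_model(), leg = "FL",
                                    dbeta_posterior = 0) {
  if (is.character(mode)) {
    is <- model$config$modes[[mode]]$intersegmental
    gmax <- if (leg == "FL") is$g_inh3 else if (leg == "ML") is$g_inh9 else
      stop("no intersegmental synapse targets the hind leg", call. = FALSE)
    pars <- list(g_inh = gmax, theta = is$theta, slope = is$slope,
                 dgate = is$dgate)
  } else pars <- mode
  w <- pars$g_inh / (1 + exp(-(beta_posterior - pars$theta) / pars$slope))
  if (isTRUE(pars$dgate > 0))
    w <- w / (1 + exp(-dbeta_posterior / 0.01))
  w
}

# default initial condition: all legs grounded, hind-leg levator neuron
# depolarised so the rhythm starts in the metathorax
initial_state <- function(model) {
  slay <- as.character(sw_state_layout()$names)
  x <- setNames(numeric(length(slay)), slay)
  x[grep("^V\\.", slay)] <- -60
  x[grep("^h\\.", slay)] <- 0.5
  x[grep("^alpha", slay)] <- 78
  x[grep("^beta", slay)] <- 30
  x[grep("^gamma", slay)] <- 77
  x["V.C15"] <- -45
  x["h.C15"] <- 0.9
  list(x = x, gs = c(1L, 1L, 1L), gf = c(1L, 1L, 1L))
}

# resolve a command list into engine events (t, idx, value); restores use the
# baseline parameter vector of the mode active at restore time
commands_to_events <- function(model, mode, commands, resolve_env) {
  lay <- as.character(sw_param_layout())
  ev <- data.frame(t = numeric(0), name = character(0), value = numeric(0),
                   command = character(0))
  cur_mode <- mode
  # commands must be processed in onset order so mode switches are tracked
  onsets <- vapply(commands, function(cm) cm$onset_ms, 0)
  for (cm in commands[order(onsets)]) {
    if (identical(cm$mechanism, "mode_switch")) {
      p_old <- param_vector(model$config, cur_mode)
      p_new <- param_vector(model$config, cm$mode)
      ch <- names(p_new)[p_new != p_old]
      if (length(ch))
        ev <- rbind(ev, data.frame(t = cm$onset_ms, name = ch,
                                   value = unname(p_new[ch]),
                                   command = cm$label))
      cur_mode <- cm$mode
      next
    }
    p_base <- param_vector(model$config, cur_mode)
    ov <- command_overrides(model, cm, p_base)
    ev <- rbind(ev, data.frame(t = cm$onset_ms, name = names(ov),
                               value = unname(ov), command = cm$label))
    if (!is.null(cm$offset_ms))
      ev <- rbind(ev, data.frame(t = cm$offset_ms, name = names(ov),
                                 value = unname(p_base[names(ov)]),
                                 command = paste0(cm$label, ":restore")))
  }
  if (nrow(ev)) {
    # contradictory overlapping rewrites of one conductance are rejected
    key <- paste(ev$t, ev$name)
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    if (any(dup)) {
      conflict <- ev[dup, ]
      bad <- tapply(conflict$value, paste(conflict$t, conflict$name),
                    function(v) length(unique(v)) > 1)
      if (any(bad))
        stop("conflicting commands rewrite conductance '",
             sub("^[0-9.]+ ", "", names(bad)[bad][1]),
             "' at the same time with different values", call. = FALSE)
    }
    ev <- ev[order(ev$t, ev$name), ]
    ev$idx <- match(ev$name, lay) - 1L
    if (anyNA(ev$idx))
      stop("unknown conductance key '", ev$name[is.na(ev$idx)][1], "'",
           call. = FALSE)
  }
  ev
}

#' Simulate a scenario
#'
#' Runs the three-leg model for `t_span` milliseconds in a given starting
#' coordination mode, applying an optional schedule of decoupling commands
#' and mode switches.  The simulation is deterministic: identical inputs
#' give bitwise-identical trajectories.
#'
#' @param model An `sw_model`.
#' @param t_span Simulated time (ms).
#' @param mode Starting coordination mode (`"tetrapod"` or `"tripod"`).
#' @param commands List of command objects created by
#'   [decouple_intersegmental()], [decouple_cpg_drive()],
#'   [decouple_premotor()] or [mode_switch()].
#' @param dt Integration step (ms).
#' @param sample_dt Output sampling interval (ms).
#' @param init Optional initial condition as returned by the internal
#'   default (list with `x`, `gs`, `gf`).
#' @param settle Settling time (ms) used when resolving onsets anchored to
#'   hind-leg lift-off.
#' @return An object of class `sw_trajectory`: list with `time`, `states`
#'   (matrix of all state variables), `kin` (data frame `t_ms`,
#'   `alpha_deg.FL`, ... for the three legs), `events` (applied parameter
#'   rewrites), `mode`, `dt`.
#' @export
simulate_scenario <- function(model, t_span = 20000, mode = "tetrapod",
                              commands = list(), dt = 0.1, sample_dt = 1,
                              init = NULL, settle = 5000) {
  stopifnot(inherits(model, "sw_model"))
  if (inherits(commands, "sw_command")) commands <- list(commands)
  commands <- resolve_onsets(model, mode, commands, settle = settle,
                             dt = dt)
  ev <- commands_to_events(model, mode, commands, NULL)
  P <- param_vector(model$config, mode)
  if (is.null(init)) init <- initial_state(model)
  res <- sw_simulate(unname(P), unname(init$x), init$gs, init$gf,
                     0, t_span, dt, sample_dt,
                     if (nrow(ev)) ev$t else numeric(0),
                     if (nrow(ev)) as.integer(ev$idx) else integer(0),
                     if (nrow(ev)) ev$value else numeric(0))
  slay <- as.character(sw_state_layout()$names)
  colnames(res$out) <- c("t", slay)
  kin <- as.data.frame(res$out[, c("t", paste0(rep(c("alpha", "beta", "gamma"),
                                                   3), ".",
                                               rep(LEGS, each = 3)))])
  names(kin)[1] <- "t_ms"
  structure(list(time = res$out[, "t"], states = res$out, kin = kin,
                 events = ev, mode = mode, commands = commands, dt = dt,
                 sample_dt = sample_dt,
                 final = list(x = res$state, gs = res$gs, gf = res$gf)),
            class = "sw_trajectory")
}

#' @export
print.sw_trajectory <- function(x, ...) {
  cat("sw_trajectory:", length(x$time), "samples,",
      max(x$time), "ms, mode", x$mode, "\n")
  if (nrow(x$events))
    cat("  parameter rewrites at t =",
        paste(unique(x$events$t), collapse = ", "), "ms\n")
  invisible(x)
}

#' Extract per-leg kinematics
#'
#' @param traj An `sw_trajectory`.
#' @param legs Legs to include.
#' @return Data frame `t_ms` plus `alpha_deg`, `beta_deg`, `gamma_deg`
#'   columns per leg.
#' @export
kinematics <- function(traj, legs = LEGS) {
  out <- data.frame(t_ms = traj$kin$t_ms)
  for (leg in legs) {
    out[[paste0("alpha_deg.", leg)]] <- traj$kin[[paste0("alpha.", leg)]]
    out[[paste0("beta_deg.", leg)]] <- traj$kin[[paste0("beta.", leg)]]
    out[[paste0("gamma_deg.", leg)]] <- traj$kin[[paste0("gamma.", leg)]]
  }
  out
}

#' Write kinematics to CSV
#'
#' @param traj An `sw_trajectory`.
#' @param path Output file.
#' @param legs Legs to include.
#' @return `path`, invisibly.
#' @export
write_kinematics_csv <- function(traj, path, legs = LEGS) {
  write.csv(kinematics(traj, legs), path, row.names = FALSE)
  invisible(path)
}

# find hind-leg lift-off times of a commands-free reference run and resolve
# anchored onsets {anchor: "HL_liftoff", offset_ms} to absolute times
resolve_onsets <- function(model, mode, commands, settle = 5000, dt = 0.1) {
  needs <- vapply(commands, function(cm) is.null(cm$onset_ms), TRUE)
  if (!any(needs)) return(commands)
  ref <- simulate_scenario(model, t_span = settle + 6000, mode = mode,
                           commands = list(), dt = dt, sample_dt = 1)
  ev <- detect_events(ref$kin$t_ms, ref$kin$beta.HL)
  lo <- ev$t[ev$kind == "liftoff" & ev$t >= settle]
  if (!length(lo))
    stop("no hind-leg lift-off found after the settling time; cannot ",
         "anchor command onsets", call. = FALSE)
  for (i in seq_along(commands)) {
    cm <- commands[[i]]
    if (is.null(cm$onset_ms)) {
      if (!identical(cm$anchor, "HL_liftoff"))
        stop("unknown onset anchor '", cm$anchor, "'", call. = FALSE)
      commands[[i]]$onset_ms <- lo[1] + cm$anchor_offset_ms
    }
  }
  commands
}
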