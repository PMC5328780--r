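#' Graded synaptic output of a nonspiking neuron
#'
#' Monotone sigmoid transfer from membrane potential to a bounded activation
#' in \[0, 1\]; the same curve gates all graded synapses in the model.
#'
#' @param V Membrane potential (mV); vectorised.
#' @param half Half-activation voltage (mV).
#' @param slope Slope factor (mV).
#' @return Activation values in \[0, 1\].
#' @export
graded_output <- function(V, half = -43, slope = 1) {
  1 / (1 + exp(-(V - half) / slope))
}

#' Time derivatives of a single model neuron
#'
#' The right-hand side of one neuron's dynamics.  CPG neurons are
#' two-variable units with a persistent inward current and slow inactivation
#' `h`:
#' \deqn{C dV/dt = -g_L (V - E_L) - g_P m_\infty(V) h (V - E_P) - I_{syn}}
#' \deqn{dh/dt = (h_\infty(V) - h) / \tau_h(V)}
#' Premotor, sensory and motoneurons are single-variable leaky units.
#'
#' @param unit List describing the unit: `kind` (one of `"cpg"`,
#'   `"premotor_in"`, `"sensory_in"`, `"motoneuron"`) and `params` (named
#'   list with `C`, `gL`, `EL` and, for CPG units, `gP`, `EP`, `th_m`,
#'   `sg_m`, `th_h`, `sg_h`, `tauh0`, `sg_th`, `th_t`).
#' @param state List with membrane potential `V` (mV) and, for CPG units,
#'   slow variable `h`.
#' @param I_syn Total synaptic plus drive current onto the unit (positive =
#'   outward).
#' @return List with `dV` (mV/ms) and, for CPG units, `dh` (1/ms).
#' @export
neuron_rhs <- function(unit, state, I_syn = 0) {
  if (!is.finite(state$V) || !is.finite(I_syn) ||
      (unit$kind == "cpg" && !is.finite(state$h)))
    stop("non-finite state for neuron '", unit$id %||% "?",
         "': numerical blow-up", call. = FALSE)
  p <- unit$params
  I <- p$gL * (state$V - p$EL) + I_syn
  if (identical(unit$kind, "cpg")) {
    minf <- 1 / (1 + exp(-(state$V - p$th_m) / p$sg_m))
    hinf <- 1 / (1 + exp((state$V - p$th_h) / p$sg_h))
    tauh <- p$tauh0 / cosh((state$V - (p$th_t %||% p$th_h)) / (2 * p$sg_th))
    I <- I + p$gP * minf * state$h * (state$V - p$EP)
    list(dV = -I / p$C, dh = (hinf - state$h) / tauh)
  } else {
    list(dV = -I / p$C)
  }
}

#' Reference fixed-step RK4 integrator for small unit networks
#'
#' A plain-R integrator over an arbitrary set of units coupled by graded
#' synapses and tonic conductance drives.  It implements exactly the same
#' equations as the compiled three-leg engine and serves as its independent
#' cross-check, and as a workbench for single neurons and isolated
#' half-centers.
#'
#' @param units Named list of units (see [neuron_rhs()]).
#' @param synapses Data frame with columns `pre`, `post`, `g`, `E` (graded
#'   synapses `I = g s(V_pre) (V_post - E)`).
#' @param drives Data frame with columns `target`, `g`, `E` (tonic
#'   conductance inputs).
#' @param x0 Named list of initial states per unit (`V`, and `h` for CPGs).
#' @param t_span Simulated time (ms), from 0.
#' @param dt Step (ms); must be positive.
#' @param sigmoid List with `half` and `slope` of the graded-output curve.
#' @param hooks Optional list of functions `f(t, tables)` where `tables` is
#'   `list(synapses=, drives=)`; whatever they return (same shape) replaces
#'   the tables at that step, so hooks can rewrite conductances over time.
#' @param sample_dt Output sampling interval (ms).
#' @return Matrix with columns `t`, then `V.<id>` and `h.<id>`.
#' @export
integrate_units <- function(units, synapses = NULL, drives = NULL, x0,
                            t_span, dt = 0.1, sigmoid = list(half = -43, slope = 1),
                            hooks = NULL, sample_dt = dt) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  ids <- names(units)
  for (id in ids) units[[id]]$id <- id
  if (is.null(synapses))
    synapses <- data.frame(pre = character(), post = character(),
                           g = numeric(), E = numeric())
  if (is.null(drives))
    drives <- data.frame(target = character(), g = numeric(), E = numeric())

  V <- vapply(ids, function(id) x0[[id]]$V, 0)
  h <- vapply(ids, function(id) x0[[id]]$h %||% NA_real_, 0)
  iscpg <- vapply(units, function(u) identical(u$kind, "cpg"), TRUE)

  n <- round(t_span / dt)
  sev <- max(1L, round(sample_dt / dt))
  keep <- seq(0L, n, by = sev)
  out <- matrix(NA_real_, length(keep), 1 + 2 * length(ids),
                dimnames = list(NULL, c("t", paste0("V.", ids), paste0("h.", ids))))
  irow <- 1L
  record <- function(t) {
    out[irow, ] <<- c(t, V, h)
    irow <<- irow + 1L
  }
  record(0)

  deriv <- function(V, h, tab) {
    s <- graded_output(V, sigmoid$half, sigmoid$slope)
    Isyn <- setNames(numeric(length(ids)), ids)
    if (nrow(tab$synapses))
      for (k in seq_len(nrow(tab$synapses))) {
        sy <- tab$synapses[k, ]
        Isyn[sy$post] <- Isyn[sy$post] + sy$g * s[sy$pre] * (V[sy$post] - sy$E)
      }
    if (nrow(tab$drives))
      for (k in seq_len(nrow(tab$drives))) {
        dr <- tab$drives[k, ]
        Isyn[dr$target] <- Isyn[dr$target] + dr$g * (V[dr$target] - dr$E)
      }
    dV <- numeric(length(ids)); dh <- numeric(length(ids))
    for (i in seq_along(ids)) {
      st <- list(V = V[i], h = if (iscpg[i]) h[i] else NULL)
      d <- neuron_rhs(units[[i]], st, Isyn[i])
      dV[i] <- d$dV
      dh[i] <- if (iscpg[i]) d$dh else 0
    }
    list(dV = dV, dh = dh)
  }

  tab <- list(synapses = synapses, drives = drives)
  for (istep in seq_len(n)) {
    t <- (istep - 1) * dt
    if (!is.null(hooks))
      for (f in hooks) {
        res <- f(t, tab)
        if (!is.null(res)) tab <- res
      }
    k1 <- deriv(V, h, tab)
    k2 <- deriv(V + dt / 2 * k1$dV, h + dt / 2 * k1$dh, tab)
    k3 <- deriv(V + dt / 2 * k2$dV, h + dt / 2 * k2$dh, tab)
    k4 <- deriv(V + dt * k3$dV, h + dt * k3$dh, tab)
    V <- V + dt / 6 * (k1$dV + 2 * k2$dV + 2 * k3$dV + k4$dV)
    h <- h + dt / 6 * (k1$dh + 2 * k2$dh + 2 * k3$dh + k4$dh)
    h[iscpg] <- pmin(pmax(h[iscpg], 0), 1)
    if (any(!is.finite(V)) || any(abs(V) > 500)) {
      bad <- ids[which(!is.finite(V) | abs(V) > 500)[1]]
      stop("numerical blow-up in unit '", bad, "' at t = ", t + dt, " ms",
           call. = FALSE)
    }
    if (istep %% sev == 0) record(istep * dt)
  }
  out
}

#' Convenience constructor for model neurons
#'
#' @param kind Unit kind; CPG units get the persistent-inward-current
#'   parameters of `config`, all other kinds are passive.
#' @param config An `sw_config` supplying the default parameters.
#' @param id Optional unit label.
#' @return A unit list usable with [neuron_rhs()] / [integrate_units()].
#' @export
make_unit <- function(kind = c("cpg", "premotor_in", "sensory_in", "motoneuron"),
                      config = default_config(), id = NULL) {
  kind <- match.arg(kind)
  np <- config$neuron
  params <- if (kind == "cpg") {
    list(C = np$C_cpg, gL = np$gL_cpg, EL = np$EL_cpg, gP = np$gP, EP = np$EP,
         th_m = np$th_m, sg_m = np$sg_m, th_h = np$th_h, sg_h = np$sg_h,
         tauh0 = np$tauh0, sg_th = np$sg_th, th_t = np$th_t)
  } else {
    list(C = np$C_pas, gL = np$gL_pas, EL = np$EL_pas)
  }
  list(id = id, kind = kind, params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
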