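#' Default model configuration
#'
#' Returns the committed baseline parameter set of the three-leg model.  All
#' conductances are keyed by their customary symbols: `g_app1` ... `g_app18`
#' are the central drives to the CPG neurons C1 ... C18 (C1-C6 front leg,
#' C7-C12 middle leg, C13-C18 hind leg; within each leg the order is
#' protractor, retractor, levator, depressor, extensor, flexor, so e.g.
#' `g_app3` drives the front-leg levator neuron C3 and `g_app15`/`g_app16`
#' the hind-leg levator/depressor pair).  `g_d*` are the tonic inhibitory
#' inputs to the premotor interneurons (the levator-depressor premotor INs of
#' the front leg are IN5/IN6, of the hind leg IN29/IN30), `g_MN` the uniform
#' excitatory motoneuron drive, and `g_inh3`/`g_inh9` the maximal
#' conductances of the intersegmental inhibitory synapses onto the levator
#' CPG neurons C3 (from the middle leg) and C9 (from the hind leg).  There is
#' no intersegmental synapse onto the hind-leg LD CPG.
#'
#' The `modes` entry holds one drive set per coordination pattern; switching
#' mode changes drives and the beta-mapping of the intersegmental synapses
#' but never the network topology.  The baseline values are calibrated so
#' that the control model steps with a period of about 1180 ms in tetrapod
#' and about 615 ms in tripod mode.
#'
#' @return A nested list of class `sw_config`.
#' @export
default_config <- function() {
  cfg <- list(
    neuron = list(
      # two-variable persistent-inward-current CPG units
      C_cpg = 21, gL_cpg = 2.8, EL_cpg = -65, gP = 10, EP = 50,
      th_m = -40, sg_m = 6, th_h = -62, sg_h = 3, tauh0 = 1620, sg_th = 5,
      th_t = -30,
      # single-variable passive units (premotor INs, sensory INs, MNs)
      C_pas = 10, gL_pas = 1, EL_pas = -60,
      # graded-output sigmoid shared by all nonspiking units
      th_s = -43, sg_s = 1,
      E_inh = -80, E_exc = 0, V_sanity = 200),
    network = list(
      g_cc = 1.5,      # mutual inhibition within each half-center
      g_cpg_in = 0.8,  # CPG neuron -> its premotor IN (inhibitory)
      g_in_tone = 1.5, # tonic excitatory conductance onto premotor INs
      g_in_mn = 4,     # premotor IN -> MN (inhibitory)
      g_MN = 1),       # uniform excitatory drive to all MNs
    muscle = list(tau_act = 20, gain_alpha = 0.56, gain_beta = 0.55,
                  gain_gamma = 0.3),
    sensory = list(
      tau_p = 150, g_sn = 3,
      g_snl_lev = 0.05, g_snl_dep = 0.25,  # lift signal -> LD CPG
      g_snt_dep = 2.5, g_snt_lev = 0.25,   # touch-down signal -> LD CPG
      g_gate = 2,                          # stance/flexion gating drive
      beta_pr_th = 33, beta_ef_th = 45, hyst = 1,
      alpha_pro_th = 36, alpha_ret_th = 120),
    modes = list(
      tetrapod = list(
        g_app = drive_set(
          lev = c(FL = -0.76, ML = 0.35, HL = 0.35),
          dep = c(FL = 0.25, ML = 0.44, HL = 0.40)),
        intersegmental = list(g_inh3 = 5, g_inh9 = 2, theta = 45,
                              slope = 1.5, E = -80, dgate = 0)),
      tripod = list(
        g_app = drive_set(
          lev = c(FL = 2.20, ML = 2.00, HL = 2.00),
          dep = c(FL = 1.55, ML = 1.48, HL = 1.42)),
        intersegmental = list(g_inh3 = 2, g_inh9 = 2, theta = 45,
                              slope = 1.5, E = -80, dgate = 0))),
    g_d = gd_set(0.9),
    decoupling = list(strong_factor = 2.3, ref_drive = 0.76, gd_strong = 4))
  class(cfg) <- "sw_config"
  cfg
}

# build the 18 g_app keys from per-leg levator/depressor values; PR and EF
# CPG pairs get a small symmetric drive (they are slaved to the sensory
# gates, not free-running)
drive_set <- function(lev, dep, pr_ef = 0.05) {
  v <- setNames(rep(pr_ef, 18), paste0("g_app", 1:18))
  for (l in seq_along(LEGS)) {
    v[paste0("g_app", 6 * (l - 1) + 3)] <- lev[[LEGS[l]]]
    v[paste0("g_app", 6 * (l - 1) + 4)] <- dep[[LEGS[l]]]
  }
  as.list(v)
}

# tonic premotor-IN inhibition, paper numbering (12 INs per leg, premotor at
# positions 1, 2, 5, 6, 7, 8)
gd_set <- function(value) {
  keys <- unlist(lapply(0:2, function(l) paste0("g_d", 12 * l + IN_NUM)))
  as.list(setNames(rep(value, length(keys)), keys))
}

#' Read / write a model configuration as YAML
#'
#' @param path File path of a YAML configuration.
#' @return `read_config()` returns an `sw_config`; `write_config()` is called
#'   for its side effect and returns `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- "sw_config"
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @param config An `sw_config` list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' The committed calibrated baseline configuration
#'
#' Reads the baseline parameter file shipped with the package
#' (`inst/extdata/baseline.yaml`), the drive calibration of which reproduces
#' the printed control periods (tetrapod about 1180 ms, tripod about 615 ms).
#'
#' @return An `sw_config`.
#' @export
baseline_config <- function() {
  path <- system.file("extdata", "baseline.yaml", package = "stickwalk")
  if (nzchar(path)) read_config(path) else default_config()
}

required_scalar_keys <- function() {
  list(neuron = c("C_cpg", "gL_cpg", "EL_cpg", "gP", "EP", "th_m", "sg_m",
                  "th_h", "sg_h", "tauh0", "sg_th", "th_t", "C_pas", "gL_pas",
                  "EL_pas", "th_s", "sg_s", "E_inh", "E_exc", "V_sanity"),
       network = c("g_cc", "g_cpg_in", "g_in_tone", "g_in_mn", "g_MN"),
       muscle = c("tau_act", "gain_alpha", "gain_beta", "gain_gamma"),
       sensory = c("tau_p", "g_sn", "g_snl_lev", "g_snl_dep", "g_snt_dep",
                   "g_snt_lev", "g_gate", "beta_pr_th", "beta_ef_th", "hyst",
                   "alpha_pro_th", "alpha_ret_th"))
}

#' Validate a configuration
#'
#' Checks that every required conductance and parameter key is present and
#' numeric, and that no intersegmental synapse is declared onto the
#' metathoracic (hind-leg) LD CPG.  Errors name the first missing key.
#'
#' @param config An `sw_config`.
#' @return The config, invisibly.
#' @export
validate_config <- function(config) {
  req <- required_scalar_keys()
  for (grp in names(req)) for (k in req[[grp]]) {
    v <- config[[grp]][[k]]
    if (is.null(v) || !is.numeric(v))
      stop("configuration is missing conductance/parameter key '", grp, "$",
           k, "'", call. = FALSE)
  }
  if (is.null(config$modes) || !length(config$modes))
    stop("configuration has no coordination modes", call. = FALSE)
  for (m in names(config$modes)) {
    md <- config$modes[[m]]
    for (k in paste0("g_app", 1:18))
      if (is.null(md$g_app[[k]]))
        stop("mode '", m, "' is missing drive key '", k, "'", call. = FALSE)
    for (k in c("g_inh3", "g_inh9", "theta", "slope", "E", "dgate"))
      if (is.null(md$intersegmental[[k]]))
        stop("mode '", m, "' is missing intersegmental key '", k, "'",
             call. = FALSE)
    bad <- intersect(c("g_inh15", "g_inh16", "g_inhHL"),
                     names(md$intersegmental))
    if (length(bad))
      stop("an intersegmental synapse onto the metathoracic LD CPG is not ",
           "permitted (offending key '", bad[1], "')", call. = FALSE)
  }
  for (k in names(gd_set(0)))
    if (is.null(config$g_d[[k]]))
      stop("configuration is missing premotor drive key '", k, "'",
           call. = FALSE)
  invisible(config)
}

# map a config + mode onto the flat engine parameter vector
param_vector <- function(config, mode) {
  if (!mode %in% names(config$modes))
    stop("unknown coordination mode '", mode, "'", call. = FALSE)
  lay <- as.character(sw_param_layout())
  p <- setNames(numeric(length(lay)), lay)
  for (grp in c("neuron", "network", "muscle", "sensory"))
    for (k in names(config[[grp]]))
      if (k %in% lay) p[k] <- config[[grp]][[k]]
  md <- config$modes[[mode]]
  for (l in 0:2) {
    leg <- LEGS[l + 1]
    for (j in 1:6) {
      # negative drive values denote an inhibitory tonic conductance
      ga <- md$g_app[[paste0("g_app", 6 * l + j)]]
      p[paste0("gappE", j, ".", leg)] <- max(ga, 0)
      p[paste0("gappI", j, ".", leg)] <- max(-ga, 0)
      p[paste0("gd", j, ".", leg)] <- config$g_d[[paste0("g_d", 12 * l + IN_NUM[j])]]
    }
    is <- md$intersegmental
    p[paste0("is_g.", leg)] <-
      if (leg == "FL") is$g_inh3 else if (leg == "ML") is$g_inh9 else 0
    p[paste0("is_theta.", leg)] <- is$theta
    p[paste0("is_slope.", leg)] <- is$slope
    p[paste0("is_E.", leg)] <- is$E
    p[paste0("is_dgate.", leg)] <- is$dgate
  }
  p["ef_inv.HL"] <- 1  # hind-leg tibia moves in anti-phase to the front legs
  p
}
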