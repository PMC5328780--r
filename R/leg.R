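#' One integration step of a muscle activation
#'
#' First-order activation dynamics `da/dt = (mn - a) / tau_act`, advanced one
#' step with the exact exponential update.
#'
#' @param a Current activation in \[0, 1\] (vectorised).
#' @param mn_output Motoneuron output in \[0, 1\].
#' @param dt Step (ms).
#' @param tau_act Activation time constant (ms).
#' @return Updated activation.
#' @export
muscle_update <- function(a, mn_output, dt, tau_act = 20) {
  stopifnot(all(mn_output >= 0 & mn_output <= 1))
  mn_output + (a - mn_output) * exp(-dt / tau_act)
}

# printed working ranges of the three joint angles (degrees)
ANGLE_RANGES <- list(alpha = c(28, 128), beta = c(30, 60), gamma = c(45, 110))

#' One integration step of the three joint angles
#'
#' Each joint moves with a velocity proportional to the difference of its
#' antagonistic muscle activations and is clamped to its working range:
#' alpha in \[28, 128\] (retractor increases alpha), beta in \[30, 60\]
#' (levator raises beta; 30 means ground contact), gamma in \[45, 110\]
#' (flexor increases gamma).
#'
#' @param angles Named numeric `c(alpha=, beta=, gamma=)` in degrees.
#' @param activations Named numeric with the six muscle activations `pro`,
#'   `ret`, `lev`, `dep`, `ext`, `flex`.
#' @param dt Step (ms).
#' @param gains Named numeric `c(alpha=, beta=, gamma=)`, maximal angular
#'   velocities (deg/ms).
#' @return Updated `angles`.
#' @export
joint_update <- function(angles, activations, dt,
                         gains = c(alpha = 0.3, beta = 0.45, gamma = 0.3)) {
  v <- c(alpha = unname(gains["alpha"] * (activations["ret"] - activations["pro"])),
         beta = unname(gains["beta"] * (activations["lev"] - activations["dep"])),
         gamma = unname(gains["gamma"] * (activations["flex"] - activations["ext"])))
  out <- angles + v * dt
  for (k in names(ANGLE_RANGES))
    out[k] <- min(max(out[k], ANGLE_RANGES[[k]][1]), ANGLE_RANGES[[k]][2])
  out
}

#' Intraleg sensory gating from the beta angle
#'
#' Updates the two discrete gating latches of a leg from the current beta
#' angle and its direction of movement, and returns the conductance routing
#' they imply for the PR and EF systems.  When beta falls below the
#' ground-contact threshold while descending, the stance latch engages:
#' excitation is routed to the retractor CPG neuron and withdrawn from the
#' protractor side.  Flexion engages earlier during the descent, at the
#' higher threshold `beta_ef_th`.  On lift-off (beta rising through the
#' ground-contact threshold plus hysteresis) both latches clear, routing
#' excitation to protraction and extension.  The metathoracic leg moves its
#' tibia in anti-phase to the other legs (`ef_invert`), so its
#' flexion routing is reversed.
#'
#' @param beta Current beta (degrees).
#' @param dbeta Current angular velocity of beta (deg/ms).
#' @param latches List with logical `stance` and `flex`.
#' @param thresholds List with `beta_pr_th`, `beta_ef_th`, `hyst`.
#' @param ef_invert Logical; reverse extensor/flexor routing (hind leg).
#' @return List with updated `latches` and `gates`, the latter giving the
#'   gating drive fraction in \[0, 1\] for `pro`, `ret`, `ext`, `flex`.
#' @export
intraleg_sensory_gate <- function(beta, dbeta, latches,
                                  thresholds = list(beta_pr_th = 33,
                                                    beta_ef_th = 45, hyst = 1),
                                  ef_invert = FALSE) {
  th <- thresholds
  if (!latches$stance && beta <= th$beta_pr_th && dbeta < 0)
    latches$stance <- TRUE
  else if (latches$stance && beta >= th$beta_pr_th + th$hyst && dbeta > 0)
    latches$stance <- FALSE
  if (!latches$flex && beta <= th$beta_ef_th && dbeta < 0)
    latches$flex <- TRUE
  else if (latches$flex && beta >= th$beta_pr_th + th$hyst && dbeta > 0)
    latches$flex <- FALSE
  fl <- if (ef_invert) !latches$flex else latches$flex
  list(latches = latches,
       gates = list(pro = as.numeric(!latches$stance),
                    ret = as.numeric(latches$stance),
                    ext = as.numeric(!fl), flex = as.numeric(fl)))
}

#' Assemble the description of one leg's control network
#'
#' Builds the unit and synapse tables of a single leg: three half-center
#' CPGs (PR, LD, EF), six premotor interneurons with tonic inhibitory drives
#' `g_d`, two sensory interneurons feeding the LD CPG pair, six motoneurons
#' under the uniform excitatory drive `g_MN`, three antagonistic muscle pairs
#' and the joint-angle state.  Unit labels follow the customary numbering
#' (CPG neurons `C1`-`C18`, premotor INs such as `IN5`/`IN6` for the
#' front-leg LD pair and `IN29`/`IN30` for the hind-leg one, motoneurons
#' `MN1P`, `MN2R`, ...).
#'
#' @param segment `"pro"`, `"meso"` or `"meta"` (front, middle, hind leg).
#' @param config An `sw_config`.
#' @param mode Coordination mode supplying the drive set.
#' @return List of class `sw_leg` with `units`, `synapses`, `drives`,
#'   `muscles` and `angles`.
#' @export
build_leg <- function(segment = c("pro", "meso", "meta"),
                      config = default_config(), mode = "tetrapod") {
  segment <- match.arg(segment)
  validate_config(config)
  l <- match(segment, c("pro", "meso", "meta")) - 1
  leg <- LEGS[l + 1]
  md <- config$modes[[mode]]
  if (is.null(md)) stop("unknown mode '", mode, "'", call. = FALSE)

  cid <- paste0("C", 6 * l + 1:6)
  inid <- paste0("IN", 12 * l + IN_NUM)
  mnid <- paste0("MN", 6 * l + 1:6, c("P", "R", "L", "D", "E", "F"))
  snid <- paste0("IN", 12 * l + 3:4) # intrasegmental sensory interneurons

  units <- data.frame(
    id = c(cid, inid, snid, mnid),
    kind = c(rep("cpg", 6), rep("premotor_in", 6), rep("sensory_in", 2),
             rep("motoneuron", 6)),
    role = c(paste0(MUSCLES, "_cpg"), paste0(MUSCLES, "_in"),
             c("lift_sense", "touchdown_sense"), paste0(MUSCLES, "_mn")),
    network = c(rep(c("PR", "PR", "LD", "LD", "EF", "EF"), 2), "LD", "LD",
                c("PR", "PR", "LD", "LD", "EF", "EF")),
    stringsAsFactors = FALSE)

  ne <- config$network
  sn <- config$sensory
  Einh <- config$neuron$E_inh
  Eexc <- config$neuron$E_exc
  synapses <- rbind(
    # mutual inhibition inside each half-center
    data.frame(pre = cid, post = cid[c(2, 1, 4, 3, 6, 5)], g = ne$g_cc,
               E = Einh, type = "inhibitory"),
    # CPG neuron inhibits the premotor IN of its own muscle path
    data.frame(pre = cid, post = inid, g = ne$g_cpg_in, E = Einh,
               type = "inhibitory"),
    # premotor IN inhibits its motoneuron
    data.frame(pre = inid, post = mnid, g = ne$g_in_mn, E = Einh,
               type = "inhibitory"),
    # sensory INs feed the LD CPG pair (lift: excite levator, inhibit
    # depressor; touch-down: the reverse)
    data.frame(pre = snid[c(1, 1, 2, 2)], post = cid[c(3, 4, 4, 3)],
               g = c(sn$g_snl_lev, sn$g_snl_dep, sn$g_snt_dep, sn$g_snt_lev),
               E = c(Eexc, Einh, Eexc, Einh),
               type = c("excitatory", "inhibitory", "excitatory", "inhibitory")))

  gd <- unlist(config$g_d[paste0("g_d", 12 * l + IN_NUM)])
  drives <- rbind(
    data.frame(target = cid, g = unlist(md$g_app[paste0("g_app", 6 * l + 1:6)]),
               E = Eexc, label = paste0("g_app", 6 * l + 1:6)),
    data.frame(target = inid, g = gd, E = Einh,
               label = paste0("g_d", 12 * l + IN_NUM)),
    data.frame(target = mnid, g = ne$g_MN, E = Eexc, label = "g_MN"))
  rownames(drives) <- NULL

  muscles <- data.frame(
    joint = rep(c("PR", "LD", "EF"), each = 2),
    muscle = MUSCLES, activation = 0,
    tau_act = config$muscle$tau_act,
    gain = rep(unlist(config$muscle[c("gain_alpha", "gain_beta",
                                      "gain_gamma")]), each = 2))

  structure(list(segment = segment, leg = leg, units = units,
                 synapses = synapses, drives = drives, muscles = muscles,
                 angles = c(alpha = 78, beta = 30, gamma = 77),
                 ef_invert = segment == "meta"),
            class = "sw_leg")
}
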