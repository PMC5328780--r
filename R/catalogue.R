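#' The scenario catalogue of decoupling experiments
#'
#' One entry per results-figure panel of the decoupling study: the control
#' run with the tetrapod-tripod transition, the three front-leg mechanisms
#' (intersegmental synapse made excitatory or blocked, phase-dependent
#' drive decoupling, premotor decoupling), the hind-leg drive and premotor
#' decouplings in both starting modes, and the middle-leg experiments.
#' Phase-sensitive scenarios carry onsets anchored to hind-leg lift-off that
#' select the documented outcome branch.
#'
#' @param t_span Run length per scenario (ms).
#' @return List of scenario specs (`id`, `mode`, `commands`, `t_span`,
#'   `expected`).
#' @export
default_catalogue <- function(t_span = 20000) {
  sc <- function(id, mode, commands, expected, t_span_ms = t_span)
    list(id = id, mode = mode, commands = commands, t_span = t_span_ms,
         expected = expected)
  list(
    sc("fig3A", "tripod", list(mode_switch("tetrapod", onset = 12000)),
       list(pattern_early = "tripod", early_window = c(4000, 12000),
            pattern = "tetrapod", window = c(17000, 26000)),
       t_span_ms = 26000),
    sc("fig3B", "tetrapod",
       list(decouple_intersegmental("FL", "make_excitatory",
                                    anchor_offset_ms = 100)),
       list(pattern = "stopped", postures = list(FL = "lifted_protracted_extended"),
            alternating = c("ML", "HL"))),
    sc("fig3C", "tetrapod",
       list(decouple_intersegmental("FL", "block", anchor_offset_ms = 100)),
       list(pattern = "stopped", postures = list(FL = "grounded_retracted_flexed"),
            alternating = c("ML", "HL"))),
    sc("fig4A", "tetrapod",
       list(decouple_cpg_drive("FL", "lift", anchor_offset_ms = 710)),
       list(pattern = "stopped", postures = list(FL = "lifted_protracted_extended"),
            alternating = c("ML", "HL"))),
    sc("fig4B", "tetrapod",
       list(decouple_cpg_drive("FL", "lift", anchor_offset_ms = 120)),
       list(pattern = "tetrapod")),
    sc("fig5", "tetrapod",
       list(decouple_premotor("FL", "lift", anchor_offset_ms = 400)),
       list(pattern = "stopped", postures = list(FL = "lifted_protracted_extended"),
            alternating = c("ML", "HL"))),
    sc("fig6A", "tripod",
       list(decouple_cpg_drive("HL", "zero", anchor_offset_ms = 50)),
       list(pattern = "stopped",
            postures = list(HL = "grounded_retracted_stretched"),
            alternating = c("FL", "ML"))),
    sc("fig6B", "tripod",
       list(decouple_cpg_drive("HL", "zero", anchor_offset_ms = -150)),
       list(pattern = "stopped", postures = list(HL = "lifted_protracted_flexed"),
            alternating = c("FL", "ML"))),
    sc("fig7A", "tripod",
       list(decouple_premotor("HL", "ground", anchor_offset_ms = 300)),
       list(pattern = "stopped",
            postures = list(HL = "grounded_retracted_stretched"),
            alternating = c("FL", "ML"))),
    sc("fig7B", "tetrapod",
       list(decouple_premotor("HL", "ground", anchor_offset_ms = 300)),
       list(pattern = "stopped",
            postures = list(HL = "grounded_retracted_stretched"),
            alternating = c("FL", "ML"), window = c(14000, 26000)),
       t_span_ms = 26000),
    sc("fig8A", "tripod",
       list(decouple_intersegmental("ML", "make_excitatory", fixed = FALSE,
                                    anchor_offset_ms = 100)),
       list(pattern = "unusual", ml_hl_sync = TRUE)),
    sc("fig8B", "tetrapod",
       list(decouple_intersegmental("ML", "make_excitatory", fixed = FALSE,
                                    anchor_offset_ms = 100)),
       list(stopped_any = "FL", postures = list(FL = "lifted_protracted_extended"),
            ml_period_ratio = c(1.6, 2.4), window = c(14000, 26000)),
       t_span_ms = 26000),
    sc("fig9A", "tripod",
       list(decouple_cpg_drive("ML", "lift", anchor_offset_ms = 100)),
       list(stopped_any = "FL",
            postures = list(FL = "lifted_protracted_extended"))),
    sc("fig9B", "tripod",
       list(decouple_cpg_drive("ML", "zero", anchor_offset_ms = 100)),
       list(fl_ml_sync = TRUE)),
    sc("fig9C", "tetrapod",
       list(decouple_cpg_drive("ML", "zero", anchor_offset_ms = 100)),
       list(window = c(14000, 26000)), t_span_ms = 26000),
    sc("fig10A", "tetrapod",
       list(decouple_premotor("ML", "ground", anchor_offset_ms = 100)),
       list(postures = list(ML = "grounded_retracted_flexed"))),
    sc("fig10B", "tripod",
       list(decouple_premotor("ML", "ground", anchor_offset_ms = 400)),
       list(postures = list(ML = "grounded_retracted_flexed"))),
    sc("fig10C", "tripod",
       list(decouple_premotor("ML", "lift", anchor_offset_ms = 100)),
       list(postures = list(ML = "lifted_protracted_extended"))))
}

# evaluate an expected-outcome descriptor against a gait summary
check_expected <- function(summary, expected, traj) {
  notes <- character(0); pass <- TRUE
  fail <- function(msg) { pass <<- FALSE; notes <<- c(notes, msg) }
  if (!is.null(expected$pattern) && summary$pattern != expected$pattern)
    fail(paste0("pattern ", summary$pattern, " != ", expected$pattern))
  if (!is.null(expected$pattern_early)) {
    early <- summarize_gait(traj, window = expected$early_window %||% c(5000, 10000))
    if (early$pattern != expected$pattern_early)
      fail(paste0("early pattern ", early$pattern, " != ",
                  expected$pattern_early))
  }
  for (leg in names(expected$postures)) {
    got <- summary$postures[[leg]]$label %||% "(stepping)"
    if (got != expected$postures[[leg]])
      fail(paste0(leg, " posture ", got, " != ", expected$postures[[leg]]))
  }
  if (!is.null(expected$stopped_any) &&
      !expected$stopped_any %in% summary$stopped)
    fail(paste0(expected$stopped_any, " not stopped"))
  if (!is.null(expected$alternating)) {
    pr <- expected$alternating
    ph <- pair_phase(summary$events[[pr[1]]]$t[summary$events[[pr[1]]]$kind == "liftoff"],
                     summary$events[[pr[2]]]$t[summary$events[[pr[2]]]$kind == "liftoff"])
    if (is.na(ph) || circ_dist(ph, 0.5) > 0.3)
      fail(paste0(pr[1], "-", pr[2], " not alternating (phase ",
                  sprintf("%.2f", ph), ")"))
  }
  if (isTRUE(expected$ml_hl_sync)) {
    ph <- summary$phases["ML_HL"]
    if (is.na(ph) || circ_dist(ph, 0) > 0.15)
      fail(sprintf("ML-HL phase %.2f not synchronous", ph))
  }
  if (isTRUE(expected$fl_ml_sync)) {
    ph <- summary$phases["FL_ML"]
    if (is.na(ph) || circ_dist(ph, 0) > 0.15)
      fail(sprintf("FL-ML phase %.2f not synchronous", ph))
  }
  if (!is.null(expected$ml_period_ratio)) {
    r <- summary$periods$ML$period / summary$periods$HL$period
    if (is.na(r) || r < expected$ml_period_ratio[1] ||
        r > expected$ml_period_ratio[2])
      fail(sprintf("ML/HL period ratio %.2f outside [%.1f, %.1f]", r,
                   expected$ml_period_ratio[1], expected$ml_period_ratio[2]))
  }
  list(pass = pass, notes = paste(notes, collapse = "; "))
}

#' Run the full scenario catalogue
#'
#' Simulates every catalogue entry, writes per-scenario kinematics CSV and
#' gait-summary JSON when `outdir` is given, and checks each outcome against
#' its expected descriptor.  A scenario that crashes is recorded as a
#' failure and the run continues.
#'
#' @param model An `sw_model`.
#' @param catalogue List of scenario specs, see [default_catalogue()].
#' @param outdir Optional output directory.
#' @return Data frame with one row per scenario: `id`, `pattern`, `pass`,
#'   `notes`.
#' @export
run_catalogue <- function(model, catalogue = default_catalogue(),
                          outdir = NULL) {
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE,
                                   recursive = TRUE)
  rows <- lapply(catalogue, function(scn) {
    res <- tryCatch({
      traj <- simulate_scenario(model, t_span = scn$t_span, mode = scn$mode,
                                commands = scn$commands)
      summ <- summarize_gait(traj, window = scn$expected$window)
      chk <- check_expected(summ, scn$expected, traj)
      if (!is.null(outdir)) {
        write_kinematics_csv(traj, file.path(outdir, paste0(scn$id, "_kin.csv")))
        gs <- list(id = scn$id, pattern = summ$pattern,
                   stopped = summ$stopped,
                   phases = as.list(summ$phases),
                   periods = lapply(summ$periods, function(p)
                     list(period = p$period, cv = p$cv, n = p$n)),
                   postures = summ$postures, pass = chk$pass,
                   notes = chk$notes)
        jsonlite::write_json(gs, file.path(outdir, paste0(scn$id, "_gait.json")),
                             auto_unbox = TRUE, digits = NA, na = "null")
      }
      data.frame(id = scn$id, pattern = summ$pattern, pass = chk$pass,
                 notes = chk$notes)
    }, error = function(e)
      data.frame(id = scn$id, pattern = NA_character_, pass = FALSE,
                 notes = paste("error:", conditionMessage(e))))
    res
  })
  do.call(rbind, rows)
}
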