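test_that("intersegmental strength is a memoryless sigmoid of the posterior beta", {
  m <- sw_model()
  w_ground <- intersegmental_strength(30, "tetrapod", m, "FL")
  w_air <- intersegmental_strength(60, "tetrapod", m, "FL")
  gmax <- m$config$modes$tetrapod$intersegmental$g_inh3
  expect_lt(w_ground, 0.01 * gmax)   # posterior grounded: anterior released
  expect_gt(w_air, 0.99 * gmax)      # posterior lifted: full inhibition
  grid <- intersegmental_strength(seq(30, 60, 0.5), "tetrapod", m, "FL")
  expect_true(all(diff(grid) >= 0))
  expect_true(all(grid >= 0 & grid <= gmax))
  # zero maximal conductance decouples the anterior leg
  expect_equal(intersegmental_strength(60, list(g_inh = 0, theta = 45,
                                                slope = 1.5, dgate = 0)), 0)
  # no synapse targets the hind leg
  expect_error(intersegmental_strength(45, "tetrapod", m, "HL"), "hind leg")
})

test_that("network topology is identical across coordination modes", {
  m <- sw_model()
  cfg_hash <- topology_hash(m)
  # mode switching only rewrites drives/mappings: same graph
  expect_identical(topology_hash(build_model(m$config)), cfg_hash)
  p_tet <- names(stickwalk:::param_vector(m$config, "tetrapod"))
  p_tri <- names(stickwalk:::param_vector(m$config, "tripod"))
  expect_identical(p_tet, p_tri)
})

test_that("a config declaring an intersegmental synapse onto the hind-leg LD CPG is rejected", {
  cfg <- baseline_config()
  cfg$modes$tetrapod$intersegmental$g_inh15 <- 1
  expect_error(build_model(cfg), "metathoracic")
})

test_that("the tetrapod control steps in hind-middle-front order with thirds lags", {
  s <- control_gait("tetrapod")
  expect_identical(s$pattern, "tetrapod")
  expect_lt(abs(s$phases[["ML_HL"]] - 1 / 3), 0.1)
  expect_lt(abs(s$phases[["FL_ML"]] - 1 / 3), 0.1)
  expect_lt(s$periods$HL$cv, 0.01)
})

test_that("the tripod control moves front and hind legs in phase, middle in anti-phase", {
  s <- control_gait("tripod")
  expect_identical(s$pattern, "tripod")
  expect_lt(min(s$phases[["FL_HL"]], 1 - s$phases[["FL_HL"]]), 0.1)
  expect_lt(abs(s$phases[["ML_HL"]] - 0.5), 0.1)
})

test_that("the half-centers stay anti-phasic in the control runs", {
  for (mode in c("tetrapod", "tripod")) {
    tr <- control_run(mode)
    keep <- tr$states[, "t"] > 2000
    for (pair in list(c("V.C15", "V.C16"), c("V.C9", "V.C10"),
                      c("V.C3", "V.C4"))) {
      sa <- graded_output(tr$states[keep, pair[1]])
      sb <- graded_output(tr$states[keep, pair[2]])
      expect_lt(mean(sa > 0.5 & sb > 0.5), 0.02)
    }
  }
})

test_that("all state bounds hold across the control runs", {
  for (mode in c("tetrapod", "tripod")) {
    tr <- control_run(mode)
    h <- tr$states[, grep("^h\\.", colnames(tr$states))]
    expect_true(all(h >= 0 & h <= 1))
    V <- tr$states[, grep("^V\\.", colnames(tr$states))]
    expect_true(all(abs(V) < 200))
    for (leg in c("FL", "ML", "HL")) {
      expect_true(all(tr$kin[[paste0("alpha.", leg)]] >= 28 &
                        tr$kin[[paste0("alpha.", leg)]] <= 128))
      expect_true(all(tr$kin[[paste0("beta.", leg)]] >= 30 &
                        tr$kin[[paste0("beta.", leg)]] <= 60))
      expect_true(all(tr$kin[[paste0("gamma.", leg)]] >= 45 &
                        tr$kin[[paste0("gamma.", leg)]] <= 110))
    }
  }
})

test_that("the committed mode transition re-coordinates within a few cycles", {
  tr <- cached("transition", simulate_scenario(
    sw_model(), t_span = 26000, mode = "tripod",
    commands = list(mode_switch("tetrapod", onset = 12000))))
  before <- summarize_gait(tr, window = c(4000, 12000))
  # three slow cycles after the switch the new pattern is established
  after <- summarize_gait(tr, window = c(12000 + 3 * 1184, 26000))
  expect_identical(before$pattern, "tripod")
  expect_identical(after$pattern, "tetrapod")
})

test_that("the middle leg takes over the rhythm when the hind leg is decoupled", {
  tr <- cached("takeover", simulate_scenario(
    sw_model(), t_span = 26000, mode = "tetrapod",
    commands = list(decouple_premotor("HL", "ground", onset = 6000))))
  keep <- tr$kin$t_ms >= 8000
  for (leg in c("FL", "ML")) {
    ev <- detect_events(tr$kin$t_ms[keep], tr$kin[[paste0("beta.", leg)]][keep])
    per <- leg_periods(ev)
    expect_gte(per$n, 11)     # at least 10 further cycles
    expect_lt(per$cv, 0.05)   # with a stable period
  }
})
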