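test_that("muscle activation follows the exact first-order response", {
  tau <- 20
  a <- 0
  for (i in 1:300) a <- muscle_update(a, 1, dt = 1, tau_act = tau)
  expect_equal(a, 1 - exp(-300 / tau), tolerance = 1e-6)
  # fixed point
  expect_equal(muscle_update(0.37, 0.37, dt = 5, tau_act = tau), 0.37)
  # step response reaches 0.95 around 3 tau
  a <- 0; t95 <- NA
  for (i in 1:200) {
    a <- muscle_update(a, 1, dt = 1, tau_act = tau)
    if (is.na(t95) && a >= 0.95) t95 <- i
  }
  expect_equal(t95, 3 * tau, tolerance = 0.05)
})

test_that("joint angles respect antagonistic drive and hard range clamps", {
  ang <- c(alpha = 78, beta = 45, gamma = 77)
  act0 <- setNames(rep(0.5, 6), c("pro", "ret", "lev", "dep", "ext", "flex"))
  expect_equal(joint_update(ang, act0, dt = 10), ang)

  # full levator activation from the ground: beta rises monotonically and
  # saturates at exactly 60
  act <- act0; act["lev"] <- 1; act["dep"] <- 0
  beta <- 30; trace <- numeric(0)
  for (i in 1:200) {
    ang2 <- joint_update(c(alpha = 78, beta = beta, gamma = 77), act, dt = 1)
    beta <- unname(ang2["beta"]); trace <- c(trace, beta)
  }
  expect_true(all(diff(trace) >= 0))
  expect_equal(max(trace), 60)
  # and the symmetric clamp at the ground
  act <- act0; act["lev"] <- 0; act["dep"] <- 1
  beta <- 60
  for (i in 1:200)
    beta <- unname(joint_update(c(alpha = 78, beta = beta, gamma = 77),
                                act, dt = 1)["beta"])
  expect_equal(beta, 30)
})

test_that("flexion engages at a higher beta threshold than retraction", {
  lat <- list(stance = FALSE, flex = FALSE)
  # beta descending from 60
  betas <- seq(60, 30, by = -0.5)
  t_flex <- NA; t_st <- NA
  for (i in seq_along(betas)) {
    r <- intraleg_sensory_gate(betas[i], dbeta = -0.5, latches = lat)
    lat <- r$latches
    if (is.na(t_flex) && lat$flex) t_flex <- betas[i]
    if (is.na(t_st) && lat$stance) t_st <- betas[i]
  }
  expect_gt(t_flex, t_st)  # flexion strictly before retraction
  expect_equal(r$gates$ret, 1)
  expect_equal(r$gates$flex, 1)
  # on lift-off both clear together
  for (b in seq(30, 60, by = 0.5)) {
    r <- intraleg_sensory_gate(b, dbeta = 0.5, latches = lat)
    lat <- r$latches
  }
  expect_false(lat$stance); expect_false(lat$flex)
  expect_equal(r$gates$pro, 1)
  expect_equal(r$gates$ext, 1)
  # the metathoracic leg reverses the tibia routing
  r2 <- intraleg_sensory_gate(30, dbeta = -1,
                              latches = list(stance = TRUE, flex = TRUE),
                              ef_invert = TRUE)
  expect_equal(r2$gates$ext, 1)
  expect_equal(r2$gates$flex, 0)
})

test_that("build_leg wires one half-center per network with inhibitory premotor paths", {
  leg <- build_leg("pro", baseline_config())
  expect_s3_class(leg, "sw_leg")
  cpg <- leg$units[leg$units$kind == "cpg", ]
  expect_equal(table(cpg$network)[["LD"]], 2)
  expect_equal(table(cpg$network)[["PR"]], 2)
  expect_equal(table(cpg$network)[["EF"]], 2)
  # premotor IN -> MN synapses are inhibitory
  in_mn <- leg$synapses[grepl("^IN", leg$synapses$pre) &
                          grepl("^MN", leg$synapses$post), ]
  expect_true(all(in_mn$type == "inhibitory"))
  # uniform excitatory MN drive
  mn_drv <- leg$drives[leg$drives$label == "g_MN", ]
  expect_equal(nrow(mn_drv), 6)
  expect_true(all(mn_drv$g == mn_drv$g[1]))
  # sensory INs feed the LD CPG pair
  sn <- leg$synapses[grepl("^IN3|^IN4", leg$synapses$pre), ]
  expect_true(all(sn$post %in% c("C3", "C4")))
  # the front-leg LD premotor interneurons carry the customary labels
  expect_true(all(c("IN5", "IN6") %in% leg$units$id))
})

test_that("a missing conductance key is a configuration error naming the key", {
  cfg <- baseline_config()
  cfg$modes$tetrapod$g_app$g_app15 <- NULL
  expect_error(build_leg("meta", cfg, "tetrapod"), "g_app15")
  cfg2 <- baseline_config()
  cfg2$g_d$g_d29 <- NULL
  expect_error(validate_config(cfg2), "g_d29")
})

test_that("an isolated hind leg steps rhythmically through the full ranges", {
  cfg <- baseline_config()
  cfg$modes$tetrapod$intersegmental$g_inh3 <- 0
  cfg$modes$tetrapod$intersegmental$g_inh9 <- 0
  tr <- simulate_scenario(build_model(cfg), t_span = 15000, mode = "tetrapod")
  keep <- tr$kin$t_ms >= 5000
  ev <- detect_events(tr$kin$t_ms[keep], tr$kin$beta.HL[keep])
  per <- leg_periods(ev)
  expect_gte(per$n, 7)
  expect_lt(per$cv, 0.01)  # deterministic rhythm, CV below 1%
  # exactly one lift-off per period: events alternate
  expect_true(all(ev$kind[seq(2, nrow(ev), 2)] != ev$kind[seq(1, nrow(ev) - 1, 2)]))
  rng <- list(alpha = c(28, 128), beta = c(30, 60), gamma = c(45, 110))
  for (a in c("alpha", "beta", "gamma")) {
    v <- tr$kin[[paste0(a, ".HL")]][keep]
    expect_equal(range(v), rng[[a]], ignore_attr = TRUE)
  }
})

test_that("without motoneuron drive the legs freeze", {
  cfg <- baseline_config()
  cfg$network$g_MN <- 0
  tr <- simulate_scenario(build_model(cfg), t_span = 6000, mode = "tetrapod")
  keep <- tr$kin$t_ms >= 3000
  mn_out <- graded_output(tr$states[keep, grep("^V\\.MN", colnames(tr$states))])
  expect_lt(max(mn_out), 0.05)
  for (leg in c("FL", "ML", "HL"))
    expect_lt(diff(range(tr$kin[[paste0("beta.", leg)]][keep])), 0.5)
})

test_that("a fully disinhibited premotor interneuron silences its motoneuron", {
  cfg <- baseline_config()
  cfg$g_d$g_d30 <- 0  # hind-leg levator premotor IN
  tr <- simulate_scenario(build_model(cfg), t_span = 8000, mode = "tetrapod")
  keep <- tr$kin$t_ms >= 3000
  lev_mn <- graded_output(tr$states[keep, "V.MN3.HL"])
  expect_lt(max(lev_mn), 0.05)
  expect_lt(max(tr$kin$beta.HL[keep]), 31)  # the leg can no longer lift
})
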