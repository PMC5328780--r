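test_that("graded output is a bounded monotone sigmoid with midpoint 1/2", {
  expect_equal(graded_output(-43), 0.5)
  expect_equal(graded_output(-1e4), 0, tolerance = 1e-12)
  expect_equal(graded_output(1e4), 1, tolerance = 1e-12)
  grid <- graded_output(seq(-120, 20, length.out = 100))
  expect_true(all(diff(grid) >= 0))
  expect_true(all(grid >= 0 & grid <= 1))
})

test_that("a passive unit at its leak reversal has zero derivative", {
  u <- make_unit("motoneuron")
  d <- neuron_rhs(u, list(V = u$params$EL), I_syn = 0)
  expect_equal(d$dV, 0)
  expect_null(d$dh)
})

test_that("non-finite states raise a blow-up error naming the unit", {
  u <- make_unit("cpg", id = "C3")
  expect_error(neuron_rhs(u, list(V = NaN, h = 0.5)), "C3")
  expect_error(neuron_rhs(u, list(V = -60, h = Inf)), "blow-up")
})

test_that("passive relaxation matches the closed form to 1e-6", {
  cfg <- default_config()
  u <- make_unit("motoneuron", cfg)
  tau <- u$params$C / u$params$gL
  V0 <- u$params$EL - 10
  out <- integrate_units(list(mn = u), x0 = list(mn = list(V = V0)),
                         t_span = 5 * tau, dt = 0.01 * tau,
                         sample_dt = 0.1 * tau)
  expected <- u$params$EL - 10 * exp(-out[, "t"] / tau)
  expect_equal(out[, "V.mn"], expected, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("a CPG unit without persistent inward current has a unique equilibrium", {
  cfg <- default_config()
  u <- make_unit("cpg", cfg)
  u$params$gP <- 0
  drv <- data.frame(target = "c", g = 0.5, E = 0)
  ends <- vapply(c(-75, -40), function(V0) {
    out <- integrate_units(list(c = u), drives = drv,
                           x0 = list(c = list(V = V0, h = 0.5)),
                           t_span = 600, dt = 0.5, sample_dt = 50)
    out[nrow(out), "V.c"]
  }, 0)
  expect_equal(ends[1], ends[2], tolerance = 1e-4)
})

test_that("a mutually inhibitory pair with equal drives oscillates in anti-phase", {
  cfg <- default_config()
  u <- make_unit("cpg", cfg)
  syn <- data.frame(pre = c("a", "b"), post = c("b", "a"),
                    g = cfg$network$g_cc, E = cfg$neuron$E_inh)
  drv <- data.frame(target = c("a", "b"), g = 0.4, E = 0)
  out <- integrate_units(list(a = u, b = u), synapses = syn, drives = drv,
                         x0 = list(a = list(V = -59, h = 0.5),
                                   b = list(V = -61, h = 0.5)),
                         t_span = 8000, dt = 0.2, sample_dt = 2)
  keep <- out[, "t"] > 2000
  sa <- graded_output(out[keep, "V.a"])
  sb <- graded_output(out[keep, "V.b"])
  # both sides burst ...
  expect_gt(mean(sa > 0.9), 0.1)
  expect_gt(mean(sb > 0.9), 0.1)
  # ... but never together
  expect_lt(mean(sa > 0.9 & sb > 0.9), 0.02)
})

test_that("the reference integrator reproduces the compiled engine on an isolated pair", {
  # silence the sensory triggers so the hind-leg LD pair is autonomous, then
  # compare its trajectory with the plain-R integrator on the same equations
  cfg <- baseline_config()
  cfg$sensory$g_sn <- 0
  for (k in c("g_snl_lev", "g_snl_dep", "g_snt_dep", "g_snt_lev"))
    cfg$sensory[[k]] <- 0
  m <- build_model(cfg)
  tr <- simulate_scenario(m, t_span = 4000, mode = "tetrapod", sample_dt = 2)

  u <- make_unit("cpg", cfg)
  syn <- data.frame(pre = c("lev", "dep"), post = c("dep", "lev"),
                    g = cfg$network$g_cc, E = cfg$neuron$E_inh)
  drv <- data.frame(target = c("lev", "dep"),
                    g = c(cfg$modes$tetrapod$g_app$g_app15,
                          cfg$modes$tetrapod$g_app$g_app16),
                    E = 0)
  out <- integrate_units(list(lev = u, dep = u), synapses = syn, drives = drv,
                         x0 = list(lev = list(V = -45, h = 0.9),
                                   dep = list(V = -60, h = 0.5)),
                         t_span = 4000, dt = 0.1, sample_dt = 2)
  expect_equal(out[, "V.lev"], tr$states[, "V.C15"], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(out[, "h.dep"], tr$states[, "h.C16"], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("identical simulations are bitwise identical", {
  m <- sw_model()
  a <- simulate_scenario(m, t_span = 3000, mode = "tetrapod")
  b <- simulate_scenario(m, t_span = 3000, mode = "tetrapod")
  expect_identical(a$states, b$states)
})

test_that("halving dt changes the baseline tetrapod period estimate by < 0.5%", {
  m <- sw_model()
  per <- vapply(c(0.1, 0.05), function(dt)
    measure_period(m, "tetrapod", t_total = 15000, settle = 5000,
                   dt = dt)$period, 0)
  expect_lt(abs(per[2] - per[1]) / per[1], 0.005)
})
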