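test_that("events are detected at known times on a synthetic square wave", {
  fx <- make_fixture(period_ms = 600, duty = 0.5, lags = c(0, 0.5, 0),
                     n_cycles = 10, dt = 1)
  ev <- detect_events(fx$t_ms, fx$beta.FL)
  expect_equal(sum(ev$kind == "liftoff"), 10)
  expect_equal(sum(ev$kind == "touchdown"), 10)
  # the front leg starts lifted (lag 0), so its first detected lift-off is
  # at the start of the second cycle
  lo <- ev$t[ev$kind == "liftoff"]
  expect_true(all(abs(lo - seq(600, by = 600, length.out = 10)) <= 1))
  # a constant trace yields no events
  expect_equal(nrow(detect_events(fx$t_ms, rep(60, nrow(fx)))), 0)
})

test_that("threshold-straddling ripple below the hysteresis does not add events", {
  fx <- make_fixture(period_ms = 600, duty = 0.5, lags = c(0, 0.5, 0),
                     n_cycles = 10, dt = 1)
  clean <- detect_events(fx$t_ms, fx$beta.HL)
  set.seed(7)
  ripple <- fx$beta.HL + 0.9 * sin(fx$t_ms / 3) *
    exp(-abs(fx$beta.HL - 33))  # ripple concentrated near the threshold
  noisy <- detect_events(fx$t_ms, ripple, hysteresis = 1)
  expect_equal(nrow(noisy), nrow(clean))
})

test_that("non-uniform sampling is rejected", {
  t <- c(0, 1, 2, 4, 5)
  expect_error(detect_events(t, c(30, 30, 60, 60, 30)), "uniform")
})

test_that("canonical lag templates classify as tripod and tetrapod", {
  expect_identical(classify_fixture(
    make_fixture(600, 0.5, c(0, 0.5, 0), n_cycles = 10))$pattern, "tripod")
  expect_identical(classify_fixture(
    make_fixture(1180, 1 / 3, c(2 / 3, 1 / 3, 0), n_cycles = 10))$pattern,
    "tetrapod")
  # middle leg synchronous with the hind leg, front leg overlapping both
  expect_identical(classify_fixture(
    make_fixture(600, 0.5, c(0.25, 0, 0), n_cycles = 10))$pattern, "unusual")
})

test_that("too few cycles raise an insufficient-data error", {
  fx <- make_fixture(600, 0.5, c(0, 0.5, 0), n_cycles = 4)
  expect_error(classify_fixture(fx), "insufficient data")
})

test_that("steady postures are labelled from the printed angle triples", {
  steady <- function(a, b, g)
    data.frame(alpha = rep(a, 100), beta = rep(b, 100), gamma = rep(g, 100))
  expect_identical(classify_posture(steady(28, 60, 45))$label,
                   "lifted_protracted_extended")
  expect_identical(classify_posture(steady(128, 30, 110))$label,
                   "grounded_retracted_flexed")
  expect_identical(classify_posture(steady(128, 30, 45))$label,
                   "grounded_retracted_stretched")
  expect_identical(classify_posture(steady(28, 60, 110))$label,
                   "lifted_protracted_flexed")
  wobble <- data.frame(alpha = 28 + sin(1:300), beta = rep(60, 300),
                       gamma = rep(45, 300))
  expect_error(classify_posture(wobble), "not steady")
})

test_that("fixtures are reproducible under a fixed seed", {
  a <- make_fixture(600, 0.5, c(0, 0.5, 0), noise = 1, seed = 42)
  b <- make_fixture(600, 0.5, c(0, 0.5, 0), noise = 1, seed = 42)
  expect_identical(a, b)
  c2 <- make_fixture(600, 0.5, c(0, 0.5, 0), noise = 1, seed = 43)
  expect_false(identical(a, c2))
})

test_that("the period estimator recovers the requested period to one sample", {
  for (p in c(600, 1180)) {
    fx <- make_fixture(p, 0.4, c(2 / 3, 1 / 3, 0), n_cycles = 12, dt = 1)
    ev <- detect_events(fx$t_ms, fx$beta.HL)
    expect_lt(abs(leg_periods(ev)$period - p), 1 + 1e-9)
  }
})

test_that("labels are recovered for all jittered fixtures near both templates", {
  # classifier round-trip: 100 random fixtures with lag jitter < 0.05
  set.seed(11)
  n_ok <- 0
  for (i in 1:100) {
    tri <- i %% 2 == 0
    base <- if (tri) c(0, 0.5, 0) else c(2 / 3, 1 / 3, 0)
    lags <- (base + runif(3, -0.045, 0.045)) %% 1
    lags <- lags - lags[3]  # hind leg anchors the cycle
    fx <- make_fixture(if (tri) 600 else 1180, if (tri) 0.5 else 1 / 3,
                       lags, n_cycles = 10, seed = i)
    got <- classify_fixture(fx)$pattern
    if (got == (if (tri) "tripod" else "tetrapod")) n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 100)
})

test_that("pairwise phases are additive modulo one", {
  set.seed(3)
  for (i in 1:10) {
    lags <- c(runif(1), runif(1), 0)
    fx <- make_fixture(800, 0.45, lags, n_cycles = 12)
    s <- classify_fixture(fx, min_cycles = 5)
    gap <- (s$phases[["FL_ML"]] + s$phases[["ML_HL"]] -
              s$phases[["FL_HL"]]) %% 1
    expect_lt(min(gap, 1 - gap), 0.02)
  }
})

test_that("stance intervals tile the record between alternating events", {
  fx <- make_fixture(600, 0.5, c(0, 0.5, 0), n_cycles = 6)
  ev <- list(HL = detect_events(fx$t_ms, fx$beta.HL))
  st <- stance_intervals(ev, window = range(fx$t_ms))
  expect_true(all(st$t_off > st$t_on))
  expect_lt(abs(sum(st$t_off - st$t_on) / diff(range(fx$t_ms)) - 0.5), 0.05)
})
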