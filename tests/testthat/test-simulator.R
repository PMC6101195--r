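test_that("model assembly validates its inputs and geometry", {
  m <- base_model_fx()
  expect_equal(m$area, pi * 70e-4 * 75e-4, tolerance = 1e-12)
  p <- base_parameters()
  p["gbar_NaF"] <- -1
  expect_error(stellate_model(p), "negative conductance")
  expect_error(stellate_model(p[-1]), "length 55|missing")
})

test_that("passive membrane rests at -77 mV and follows RC closed forms", {
  pm <- passive_model_fx()
  st <- settle(pm, duration = 1000, dt = 0.025)
  expect_equal(st[["V"]], -77, tolerance = 1e-6)

  # +100 pA step: exponential charging with tau = Rm Cm = 40 ms towards
  # I * R_in = I * Rm / area
  r_in <- pm$params[["Rm"]] * 1000 / pm$area / 1e6  # MOhm
  tr <- simulate(pm, stimulus = step_stimulus(100, 400), dt = 0.025,
                 init = st)
  dV <- tr$V - (-77)
  dV_inf <- 100e-12 * r_in * 1e6 * 1000  # mV
  expect_equal(mean(tail(dV, 100)), dV_inf, tolerance = 0.01)
  at_tau <- dV[which.min(abs(tr$t - 40))]
  expect_equal(at_tau, dV_inf * (1 - exp(-1)), tolerance = 0.01)

  # measured input resistance matches Rm / area within 1%
  rin <- measure_rin(pm, st, dt = 0.05)
  expect_equal(rin$R_in, r_in, tolerance = 0.01)
  expect_false(rin$spiked)
})

test_that("passive impedance matches the analytic RC profile", {
  pm <- passive_model_fx()
  st <- settle(pm, duration = 1000, dt = 0.05)
  imp <- measure_impedance(pm, st, dt = 0.05)
  ana <- rc_impedance(imp$profile$f)
  expect_lt(max(abs(imp$profile$Zmag / ana$mag - 1)), 0.02)
  expect_lt(max(abs(imp$profile$phase - ana$phase)), 0.02)
  # no resonance: |Z| decreases, f_R pinned at the band floor, Q_R ~ 1,
  # and a strictly lagging phase gives zero inductive area
  expect_equal(imp$f_R, min(imp$profile$f))
  expect_equal(imp$Q_R, 1, tolerance = 0.02)
  expect_lt(imp$Phi_L, 1e-3)
})

test_that("integration is deterministic and settling is a fixed point", {
  m <- base_model_fx()
  st <- initial_state(m)
  tr1 <- simulate(m, stimulus = step_stimulus(50, 100), dt = 0.05, init = st)
  tr2 <- simulate(m, stimulus = step_stimulus(50, 100), dt = 0.05, init = st)
  expect_identical(tr1$V, tr2$V)

  s1 <- settle(m, duration = 5000, dt = 0.05)
  s2 <- settle(m, duration = 1000, dt = 0.05, init = s1)
  # the slow NaP inactivation and SK unbinding leave a residual creep of a
  # few thousandths of a mV per second at 5 s; the settled state is a fixed
  # point at that tolerance
  expect_lt(max(abs(unclass(s2) - unclass(s1))), 0.01)
  # zero stimulus from the settled state keeps V constant
  tr <- simulate(m, stimulus = zero_stimulus(500), dt = 0.05, init = s1)
  expect_lt(diff(range(tr$V)), 0.01)
})

test_that("stimulus constructors produce the specified waveforms", {
  ch <- sample_stimulus(chirp_stimulus(), dt = 0.025)
  expect_equal(max(ch), 20, tolerance = 1e-3)
  expect_equal(min(ch), -20, tolerance = 1e-3)
  # instantaneous frequency at t = 7.5 s is 7.5 Hz: period between zero
  # crossings around mid-sweep is ~1/7.5 s
  t <- (seq_along(ch) - 1) * 0.025
  mid <- which(t >= 7400 & t <= 7600)
  zc <- which(diff(sign(ch[mid])) != 0)
  period_ms <- 2 * median(diff(zc)) * 0.025
  expect_equal(1000 / period_ms, 7.5, tolerance = 0.05)

  g1 <- sample_stimulus(gwn_stimulus(100, 25000, seed = 5), dt = 0.025)
  g2 <- sample_stimulus(gwn_stimulus(100, 25000, seed = 5), dt = 0.025)
  expect_identical(g1, g2)
  expect_equal(sd(g1), 100, tolerance = 0.01)
  expect_equal(mean(g1), 0, tolerance = 1)

  s <- sample_stimulus(step_stimulus(-200, 1000, onset = 100, tail = 50),
                       dt = 0.5)
  expect_equal(sum(s == -200), 2000)
  expect_equal(length(s), 2300)
  expect_error(step_stimulus(100, -5), "positive")
})

test_that("halving the step size leaves measurements within 1%", {
  m <- base_model_fx()
  for (dt in c(0.025, 0.0125)) {
    st <- settle(m, dt = dt)
    key <- paste0("conv_", dt)
    .fixture_env[[key]] <- list(
      rmp = measure_rmp(simulate(m, stimulus = zero_stimulus(1000), dt = dt,
                                 init = st, t0 = 5000),
                        window = c(5000, 6000)),
      sag = measure_sag(simulate(m,
        stimulus = step_stimulus(-200, 1000, onset = 100, tail = 50),
        dt = dt, init = st, record_stride = max(1L, round(0.25 / dt))),
        onset = 100)$Sag,
      imp = measure_impedance(m, st, dt = dt))
  }
  a <- .fixture_env[["conv_0.025"]]
  b <- .fixture_env[["conv_0.0125"]]
  expect_equal(a$rmp$V_RMP, b$rmp$V_RMP, tolerance = 0.01)
  expect_equal(a$sag, b$sag, tolerance = 0.01)
  expect_equal(a$imp$f_R, b$imp$f_R, tolerance = 0.01)
  expect_equal(a$imp$Q_R, b$imp$Q_R, tolerance = 0.01)
})
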