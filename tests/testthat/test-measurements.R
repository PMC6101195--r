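test_that("resting potential measurement recovers constructed ground truth", {
  tr <- synthetic_trace("flat", duration = 6000, level = -62)
  r <- measure_rmp(tr)
  expect_equal(r$V_RMP, -62)
  expect_equal(r$V_SD, 0)
  # a 1-mV-amplitude sinusoid has RMS (= SD) 1/sqrt(2)
  tr2 <- synthetic_trace("mpo", duration = 6000, level = -62, amp_pp = 2,
                         freq = 8, dt = 0.125)
  expect_equal(measure_rmp(tr2)$V_SD, 1 / sqrt(2), tolerance = 1e-3)
  # measurements are invariant to the absolute time offset
  tr3 <- synthetic_trace("flat", duration = 1000, level = -62, t0 = 5000)
  expect_equal(measure_rmp(tr3)$V_RMP, -62)
  expect_error(measure_rmp(synthetic_trace("flat", duration = 100)),
               "window")
})

test_that("sag ratio recovers constructed and RC ground truth", {
  tr <- synthetic_trace("sag", duration = 1300, level = -62, onset = 100,
                        v_peak = -20, v_ss = -10, dt = 0.05)
  expect_equal(measure_sag(tr, onset = 100)$Sag, 0.5, tolerance = 1e-3)
  # a monoexponential RC response has no sag: ratio 1
  pm <- passive_model_fx()
  st <- settle(pm, duration = 500, dt = 0.05)
  rc <- simulate(pm, stimulus = step_stimulus(-200, 1000, onset = 100,
                                              tail = 50),
                 dt = 0.05, init = st, record_stride = 5)
  expect_equal(measure_sag(rc, onset = 100)$Sag, 1, tolerance = 1e-3)
  flat <- synthetic_trace("flat", duration = 1300)
  expect_error(measure_sag(flat, onset = 100), "deflection")
})

test_that("input resistance fit recovers a constructed 50 MOhm slope", {
  I <- seq(-100, 100, by = 20)
  dV <- 50 * I / 1000  # 50 MOhm in mV per pA
  expect_equal(rin_fit(I, dV), 50)
  expect_equal(rin_fit(I, dV + 3), 50)  # offset does not bias the slope
})

test_that("spike detection counts threshold crossings with a lockout", {
  expect_equal(count_spikes(synthetic_trace("flat", duration = 1000)), 0)
  times <- seq(100, 900, by = 100)  # 9 spikes
  tr <- synthetic_trace("spikes", duration = 1000, dt = 0.05,
                        spike_times = times, peak = 20)
  expect_equal(count_spikes(tr), 9)
  expect_equal(detect_spikes(tr), times, tolerance = 0.1)
  expect_equal(count_spikes(tr, window = c(250, 650)), 4)
  expect_equal(measure_vap(tr, v_rmp = -62), 20 - (-62), tolerance = 0.01)
  expect_error(measure_vap(synthetic_trace("flat", duration = 100), -62),
               "no action potential")
})

test_that("oscillation spectrum recovers an 8-Hz, 4-mV construction", {
  tr <- synthetic_trace("mpo", duration = 3000, dt = 0.25, level = -55,
                        freq = 8, amp_pp = 4)
  m <- mpo_measurements(tr$V, 0.25)
  expect_equal(m$f_MPO, 8, tolerance = 1e-6)
  expect_equal(m$V_MPO, 4, tolerance = 1e-3)
  expect_equal(m$V_avg, -55, tolerance = 1e-6)
  expect_equal(m$amplitude, 2, tolerance = 1e-3)
  # a flat segment has no spectral peak: reported as non-oscillatory
  expect_equal(mpo_measurements(rep(-60, 12000), 0.25)$f_MPO, 0)
})

test_that("impedance metrics recover a constructed band-pass profile", {
  # build a voltage response with a known transfer function peaking at 7 Hz
  dt <- 0.25
  I <- sample_stimulus(chirp_stimulus(), dt = dt)
  n <- length(I)
  f <- (seq_len(n) - 1) / (n * dt / 1000)
  f_sym <- pmin(f, 1000 / dt - f)  # Hermitian frequency axis
  H <- 50 / (1 + ((f_sym - 7) / 3)^2)
  V <- Re(fft(fft(I) * H, inverse = TRUE)) / n / 1000  # MOhm * pA -> mV
  tr <- trace_from_samples(V, dt_record = dt, I = I)
  prof <- impedance_profile(tr)
  met <- impedance_metrics(prof)
  expect_equal(met$f_R, 7, tolerance = 0.1)
  expect_equal(max(prof$Zmag), 50, tolerance = 0.01)
  expect_equal(met$Q_R, 50 / (50 / (1 + ((0.5 - 7) / 3)^2)),
               tolerance = 0.01)
})

test_that("suprathreshold and subthreshold sweeps separate cleanly", {
  ms <- base_measurements_fx()
  sw <- ms$mpo
  # no sweep sits in the forbidden amplitude gap without containing spikes
  gap <- sw$V_MPO > 30 & sw$V_MPO < 55
  expect_true(all(!gap | sw$n_spikes > 0))
  # sweeps with window spikes form the high-amplitude cluster
  expect_true(all(sw$V_MPO[sw$n_spikes > 0] > 60))
  expect_true(all(sw$V_MPO[sw$n_spikes == 0] < 25))
})
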