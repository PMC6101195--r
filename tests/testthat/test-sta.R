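# Build an sta_kernel object directly from constructed samples.
kernel_from_samples <- function(current, dt = 0.25, window = 300) {
  structure(list(lag = seq(-window / dt, 0) * dt, current = current,
                 smoothed = current, n_spikes = 1, dt = dt,
                 sigma = NA_real_),
            class = "sta_kernel")
}

test_that("the STA of a single spike is its pre-spike current segment", {
  dt <- 0.5
  I <- sin(seq(0, 40 * pi, length.out = 2001))  # arbitrary waveform
  k <- compute_sta(I, spike_times = 800, dt = dt, window = 300)
  seg <- I[(round(800 / dt) + 1 - 600):(round(800 / dt) + 1)]
  expect_equal(k$current, seg)
  expect_equal(k$n_spikes, 1)
  expect_equal(range(k$lag), c(-300, 0))
  # spikes without a full history are excluded
  k2 <- compute_sta(I, spike_times = c(100, 800), dt = dt, window = 300)
  expect_equal(k2$n_spikes, 1)
  expect_error(compute_sta(I, spike_times = 100, dt = dt), "full")
})

test_that("constant current with periodic spikes gives a flat kernel", {
  I <- rep(42, 40000)
  k <- compute_sta(I, spike_times = seq(400, 900, by = 100), dt = 0.1)
  expect_true(all(k$current == 42))
  expect_true(all(k$smoothed == 42))
})

test_that("the STA spectrum localizes a constructed 8-Hz Gabor carrier", {
  dt <- 0.25
  lag <- seq(-1200, 0) * dt
  gabor <- 50 * exp(-((lag + 60) / 50)^2) * cos(2 * pi * 8 * (lag + 60) / 1000)
  k <- kernel_from_samples(gabor, dt = dt)
  sp <- sta_spectrum(k)
  expect_equal(sp$f_STA, 8, tolerance = 0.5)
  expect_gt(sp$Q_STA, 1)
  # metrics are invariant to uniform scaling of the kernel
  k3 <- kernel_from_samples(3 * gabor, dt = dt)
  sp3 <- sta_spectrum(k3)
  expect_equal(sp3$f_STA, sp$f_STA)
  expect_equal(sp3$Q_STA, sp$Q_STA)
  # an all-positive monotone kernel is low-pass: peak at the band floor
  mono <- exp(lag / 80)
  spm <- sta_spectrum(kernel_from_samples(mono, dt = dt))
  expect_equal(spm$f_STA, 0.5, tolerance = 0.3)
  expect_equal(spm$Q_STA, 1, tolerance = 0.05)
})

test_that("temporal metrics recover constructed lobe geometry", {
  dt <- 0.25
  lag <- seq(-1200, 0) * dt
  # rectangular positive lobe of width 10 ms next to the spike
  rect <- ifelse(lag >= -10, 100, -1)
  mr <- sta_temporal_metrics(kernel_from_samples(rect, dt = dt))
  expect_equal(mr$T_TCDW, 10, tolerance = 2 * dt)
  expect_equal(mr$I_STA_peak, 100)
  # half-cosine lobe: compare against a fine-grid quadrature oracle
  Tl <- 20
  half_cos <- ifelse(lag >= -Tl, 80 * cos(pi * lag / (2 * Tl)), -5)
  mc <- sta_temporal_metrics(kernel_from_samples(half_cos, dt = dt))
  tt <- seq(-Tl, 0, by = 1e-4)
  ss <- 80 * cos(pi * tt / (2 * Tl))
  oracle <- sqrt(sum(tt^2 * ss^2) / sum(ss^2))
  expect_equal(mc$T_TCDW, Tl, tolerance = 2 * dt)
  expect_equal(mc$T_ECDW, oracle, tolerance = 0.02)
  expect_lte(mc$T_ECDW, mc$T_TCDW)
  # scaling leaves the windows unchanged and scales the peak linearly
  mc3 <- sta_temporal_metrics(kernel_from_samples(3 * half_cos, dt = dt))
  expect_equal(mc3$T_TCDW, mc$T_TCDW)
  expect_equal(mc3$T_ECDW, mc$T_ECDW)
  expect_equal(mc3$I_STA_peak, 3 * mc$I_STA_peak)
  # no positive spike-proximal lobe is an error
  expect_error(sta_temporal_metrics(kernel_from_samples(-rect, dt = dt)),
               "positive")
})

test_that("the STA of a thresholded leaky integrator recovers its filter", {
  # toy neuron: exponentially filtered Gaussian noise with threshold
  # crossings as spikes; the STA is dominated by the (time-reversed) filter
  set.seed(60)
  dt <- 0.5
  n <- 1200000
  tau <- 20
  I <- rnorm(n)
  v <- stats::filter(I, exp(-dt / tau), method = "recursive")
  theta <- 2.8 * sd(v, na.rm = TRUE)
  up <- which(v[-1] >= theta & v[-n] < theta) + 1
  up <- up[c(TRUE, diff(up) > 40 / dt)]
  spikes <- (up - 1) * dt
  expect_gt(length(spikes), 200)
  k <- compute_sta(I, spikes, dt = dt, window = 300)
  sel <- k$lag <= -1 & k$lag >= -3 * tau
  expect_gt(cor(k$current[sel], exp(k$lag[sel] / tau)), 0.9)
})

test_that("noise calibration fails cleanly when the target is unreachable", {
  pm <- passive_model_fx()
  expect_error(calibrate_sigma(pm, duration = 2000, dt = 0.1,
                               sigma_range = c(10, 20)),
               "unreachable")
  # with infinite tolerance the first probe is accepted
  s <- calibrate_sigma(base_model_fx(), tol = Inf, duration = 1000,
                       dt = 0.1, sigma_range = c(500, 1500))
  expect_equal(as.numeric(s), 1000)
})
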