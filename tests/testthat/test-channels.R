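test_that("steady-state gating curves hit their half points and limits", {
  expect_equal(gate_steady_state("NaF_m", -26.1), 0.5)
  # HCN fast at its half-voltage: the fractional power applies to the whole
  # sigmoid bracket, (1 + exp(0))^(-1.36) = 2^(-1.36)
  expect_equal(gate_steady_state("HCN_mf", -74.2), 2^-1.36, tolerance = 1e-12)
  # KA inactivation saturates at hyperpolarized potentials
  expect_gt(gate_steady_state("KA_h", -100), 0.99)
  expect_lt(gate_steady_state("KA_h", 0), 0.01)
  # KM slope is negative as defined: activation grows with depolarization
  expect_gt(gate_steady_state("KM_m", 0), gate_steady_state("KM_m", -80))
})

test_that("steady states and time constants are well behaved over voltage", {
  V <- seq(-120, 60, by = 0.5)
  for (g in c("NaF_m", "NaF_h", "KDR_n", "HCN_mf", "HCN_ms", "NaP_m",
              "NaP_h", "KA_m", "KA_h", "HVA_m", "HVA_h", "LVA_m", "LVA_h",
              "KM_m")) {
    inf <- gate_steady_state(g, V)
    tau <- gate_time_constant(g, V)
    expect_true(all(inf >= 0 & inf <= 1), info = g)
    expect_true(all(is.finite(tau) & tau > 0), info = g)
  }
})

test_that("voltage-independent calcium-channel time constants scale with F", {
  expect_equal(gate_time_constant("HVA_m", -63), 0.92)
  expect_equal(gate_time_constant("HVA_h", 10), 250)
  p <- base_parameters()
  p["Fm_HVA"] <- 1.2
  p["Fh_HVA"] <- 0.8
  expect_equal(gate_time_constant("HVA_m", -63, p), 0.92 * 1.2)
  expect_equal(gate_time_constant("HVA_h", -63, p), 250 * 0.8)
})

test_that("removable singularities of the rate functions are analytic", {
  # NaF activation forward rate is singular at V = -33 mV; the implementation
  # must equal the two-sided numerical limit
  t0 <- gate_time_constant("NaF_m", -33)
  tm <- gate_time_constant("NaF_m", -33 - 1e-4)
  tp <- gate_time_constant("NaF_m", -33 + 1e-4)
  expect_true(is.finite(t0) && t0 > 0)
  expect_equal(t0, (tm + tp) / 2, tolerance = 1e-6)
  # same structure for KDR (V = -38) and NaP activation (V = -38)
  for (g in c("KDR_n", "NaP_m")) {
    t0 <- gate_time_constant(g, -38)
    expect_equal(t0, (gate_time_constant(g, -38 - 1e-4) +
                      gate_time_constant(g, -38 + 1e-4)) / 2,
                 tolerance = 1e-6, info = g)
  }
})

test_that("Ohmic currents follow g * gates * (V - E)", {
  expect_equal(ohmic_current(3.2, 0.5^4, -90, -90), 0)   # zero driving force
  expect_equal(ohmic_current(4.2, 1, 0, 50), 4.2 * (0 - 50) * 1e-3)
  expect_equal(ohmic_current(10, 0, -20, -90), 0)        # closed gates
})

test_that("GHK calcium current reverses at the Nernst potential", {
  const <- stellate_constants()
  v_rev <- 1000 * 8.314462618 * const$temperature /
    (2 * const$Faraday) * log(const$Ca_out / const$Ca_inf)
  expect_equal(ghk_current(0.18, 1, v_rev, const$Ca_inf, const$Ca_out), 0,
               tolerance = 1e-10)
  # inward below reversal, outward above; exactly one sign change
  V <- seq(-100, 150, by = 0.5)
  I <- ghk_current(1, 1, V, const$Ca_inf, const$Ca_out)
  expect_lt(ghk_current(1, 1, -60, const$Ca_inf, const$Ca_out), 0)
  expect_equal(sum(diff(sign(I)) != 0), 1)
  # continuous through the V = 0 singularity
  expect_equal(ghk_current(1, 1, 0, 1e-4, 2),
               (ghk_current(1, 1, -1e-6, 1e-4, 2) +
                ghk_current(1, 1, 1e-6, 1e-4, 2)) / 2, tolerance = 1e-9)
})

test_that("LVA calcium-dependent inactivation follows the printed form", {
  expect_equal(lva_ca_inactivation(0), 1)
  expect_equal(lva_ca_inactivation(0.001), 0.5)
  expect_equal(lva_ca_inactivation(1e-4), 0.001 / 0.0011)
  expect_true(all(diff(lva_ca_inactivation(seq(0, 0.01, by = 1e-4))) < 0))
})

test_that("SK generator conserves probability and closes at zero calcium", {
  Q <- sk_rate_matrix(5e-4)
  expect_equal(rowSums(Q), rep(0, 6), tolerance = 1e-15, ignore_attr = TRUE)
  expect_equal(sum(sk_steady_state(3e-4)), 1, tolerance = 1e-9)
  expect_equal(sk_open_fraction_ss(0), 0)
  # open fraction is nondecreasing in calcium
  op <- sk_open_fraction_ss(c(0, 1e-5, 1e-4, 5e-4, 1e-3, 1e-2))
  expect_true(all(diff(op) >= 0))
  expect_error(sk_rate_matrix(-1), "scalar")
})

test_that("SK stationary distribution matches master-equation relaxation", {
  ca <- 1e-3  # 1 uM
  Q <- sk_rate_matrix(ca)
  derivs <- function(t, s, parms) list(as.numeric(s %*% Q))
  out <- deSolve::ode(y = c(1, 0, 0, 0, 0, 0), times = c(0, 5e5),
                      func = derivs, parms = NULL,
                      rtol = 1e-12, atol = 1e-12)
  relaxed <- out[2, -1]
  expect_equal(unname(relaxed), unname(sk_steady_state(ca)),
               tolerance = 1e-6)
})

test_that("calcium derivative has the printed fixed point and signs", {
  const <- stellate_constants()
  expect_equal(ca_derivative(const$Ca_inf, 0, 78), 0)
  expect_equal(ca_derivative(2 * const$Ca_inf, 0, 78), -const$Ca_inf / 78)
  # inward (negative) calcium current raises cytosolic calcium
  expect_gt(ca_derivative(const$Ca_inf, -0.01, 78), 0)
  expect_equal(ca_derivative(1e-4, -1, 78) - ca_derivative(1e-4, 0, 78),
               10000 / (36 * 0.1 * const$Faraday))
})
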