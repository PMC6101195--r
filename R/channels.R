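# Channel kinetics: steady states, time constants, current densities, the
# calcium pool, and the six-state Markov SK channel. These mirror the
# compiled integrator exactly (both call into the same C++ rate functions),
# so tests against these functions cover the simulator's kinetics.

GATE_NAMES <- c("NaF_m", "NaF_h", "KDR_n", "HCN_mf", "HCN_ms", "NaP_m",
                "NaP_h", "KA_m", "KA_h", "HVA_m", "HVA_h", "LVA_m", "LVA_h",
                "KM_m")

#' Steady-state value of a gating particle
#'
#' Evaluates the voltage-dependent steady state of one of the 14
#' Hodgkin-Huxley gating particles of the model. HCN activation applies its
#' fractional power (-1.36 fast, -58.5 slow) to the whole sigmoid bracket;
#' the KM slope is negative by definition so KM activates with
#' depolarization.
#'
#' @param gate One of `"NaF_m"`, `"NaF_h"`, `"KDR_n"`, `"HCN_mf"`,
#'   `"HCN_ms"`, `"NaP_m"`, `"NaP_h"`, `"KA_m"`, `"KA_h"`, `"HVA_m"`,
#'   `"HVA_h"`, `"LVA_m"`, `"LVA_h"`, `"KM_m"`.
#' @param V Membrane potential, mV (vectorized).
#' @param params Parameter vector (55, canonical order); defaults to the base
#'   model.
#' @param ka_betah_as_printed Use the literal `(V+8.2)` form of the KA
#'   inactivation backward rate instead of the symmetric `(V+58)` default.
#' @return Steady-state fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' gate_steady_state("NaF_m", -26.1)  # half-activation at the base V_half
gate_steady_state <- function(gate, V, params = base_parameters(),
                              ka_betah_as_printed = FALSE) {
  gate <- match.arg(gate, GATE_NAMES)
  p <- as_param_vector(params)
  vapply(V, function(v) {
    .gate_rates_cpp(p, v, ka_betah_as_printed)$inf[[gate]]
  }, numeric(1))
}

#' Time constant of a gating particle
#'
#' Voltage-dependent time constant (ms) of one of the 14 gating particles,
#' including the per-parameter-vector scale factors. Rate functions with
#' removable singularities (e.g. the NaF activation forward rate at
#' V = -33 mV) are evaluated by their analytic limit.
#'
#' @inheritParams gate_steady_state
#' @return Time constant(s), ms (strictly positive).
#' @export
#' @examples
#' gate_time_constant("HVA_m", -60)  # 0.92 ms, voltage independent
gate_time_constant <- function(gate, V, params = base_parameters(),
                               ka_betah_as_printed = FALSE) {
  gate <- match.arg(gate, GATE_NAMES)
  p <- as_param_vector(params)
  vapply(V, function(v) {
    .gate_rates_cpp(p, v, ka_betah_as_printed)$tau[[gate]]
  }, numeric(1))
}

#' Ohmic current density
#'
#' Current density through an Ohmic channel,
#' `I = g_max * prod(gates) * (V - E_rev)`, with `g_max` in mS/cm2 and the
#' gate product supplied with its exponents already applied.
#'
#' @param g_max Maximal conductance density, mS/cm2.
#' @param gates Product of gate variables (with their exponents).
#' @param V Membrane potential, mV.
#' @param E_rev Reversal potential, mV.
#' @return Current density, mA/cm2 (positive outward).
#' @export
ohmic_current <- function(g_max, gates, V, E_rev) {
  stopifnot(all(g_max >= 0))
  g_max * gates * (V - E_rev) * 1e-3
}

#' Goldman-Hodgkin-Katz calcium current density
#'
#' Current density through a calcium channel in GHK form. The channel's
#' conductance-like parameter scales a GHK driving-force term with units of
#' mV (so the scale keeps conductance-density units, mS/cm2, and the product
#' is a current density exactly as in the Ohmic convention). The zero-current
#' potential equals the calcium Nernst potential `(RT/2F) log(Ca_o/Ca_i)`;
#' the current is negative (inward) below it. The removable singularity at
#' V = 0 is evaluated by its analytic limit.
#'
#' @param g_scale Permeability scale, mS/cm2.
#' @param gates Product of gate variables (with exponents and any
#'   calcium-dependent inactivation applied).
#' @param V Membrane potential, mV (vectorized).
#' @param ca_i Cytosolic calcium, mM.
#' @param ca_o Extracellular calcium, mM.
#' @return Current density, mA/cm2.
#' @export
#' @examples
#' ghk_current(0.18, 1, -60, 1e-4, 2) < 0  # inward below reversal
ghk_current <- function(g_scale, gates, V, ca_i = 1e-4, ca_o = 2) {
  stopifnot(ca_i > 0, ca_o > 0, all(g_scale >= 0))
  df <- vapply(V, .ghk_df_cpp, numeric(1), cai = ca_i, cao = ca_o)
  g_scale * gates * df * 1e-3
}

#' Calcium-dependent inactivation of the LVA channel
#'
#' `s([Ca]_c) = 0.001 / (0.001 + [Ca]_c)` with calcium in mM.
#'
#' @param ca Cytosolic calcium, mM (vectorized, `>= 0`).
#' @return Fraction in `(0, 1]`, decreasing in calcium.
#' @export
lva_ca_inactivation <- function(ca) {
  stopifnot(all(ca >= 0))
  0.001 / (0.001 + ca)
}

#' Transition-rate matrix of the six-state SK channel
#'
#' The SK channel is a calcium-gated Markov scheme with four sequential
#' calcium-binding closed states (forward rate `alpha * [Ca]` with alpha per
#' uM per s, backward rate `beta`) and two open states reached from the last
#' two closed states (`gamma` forward, `delta` backward). States are ordered
#' `C1, C2, C3, C4, O1, O2`; rates are returned in ms^-1 on the model's time
#' base.
#'
#' @param ca Cytosolic calcium, mM (`>= 0`).
#' @return A 6 x 6 generator matrix `Q` (rows sum to zero; `Q[i, j]` is the
#'   rate from state i to state j).
#' @export
sk_rate_matrix <- function(ca) {
  if (length(ca) != 1L || is.na(ca) || ca < 0) stop("ca must be a scalar >= 0")
  k <- stellate_constants()$sk_rates
  kon <- k[["alpha"]] * (ca * 1000) / 1000  # per-uM-per-s * uM -> ms^-1
  koff <- k[["beta"]] / 1000
  gam <- k[["gamma"]] / 1000
  del <- k[["delta"]] / 1000
  Q <- matrix(0, 6, 6,
              dimnames = list(c("C1", "C2", "C3", "C4", "O1", "O2"),
                              c("C1", "C2", "C3", "C4", "O1", "O2")))
  Q["C1", "C2"] <- kon;  Q["C2", "C1"] <- koff
  Q["C2", "C3"] <- kon;  Q["C3", "C2"] <- koff
  Q["C3", "C4"] <- kon;  Q["C4", "C3"] <- koff
  Q["C3", "O1"] <- gam;  Q["O1", "C3"] <- del
  Q["C4", "O2"] <- gam;  Q["O2", "C4"] <- del
  diag(Q) <- -rowSums(Q)
  Q
}

#' Steady-state occupancies and open fraction of the SK channel
#'
#' The stationary distribution is obtained from the null space of the
#' generator (solving `pi Q = 0` with the conservation constraint
#' `sum(pi) = 1`). At zero calcium no binding is possible and the channel is
#' fully closed.
#'
#' @param ca Cytosolic calcium, mM (`>= 0`).
#' @return `sk_steady_state()`: named occupancy vector (sums to 1);
#'   `sk_open_fraction_ss()`: the stationary open fraction `O1 + O2`.
#' @export
sk_steady_state <- function(ca) {
  Q <- sk_rate_matrix(ca)
  A <- rbind(t(Q), rep(1, 6))
  b <- c(rep(0, 6), 1)
  pi <- qr.solve(A, b)
  pi[pi < 0 & pi > -1e-12] <- 0
  setNames(pi / sum(pi), colnames(Q))
}

#' @rdname sk_steady_state
#' @export
sk_open_fraction_ss <- function(ca) {
  vapply(ca, function(c1) {
    s <- sk_steady_state(c1)
    s[["O1"]] + s[["O2"]]
  }, numeric(1))
}

#' Time derivative of cytosolic calcium
#'
#' `d[Ca]_c/dt = -10000 I_Ca / (36 dpt F) + ([Ca]_inf - [Ca]_c) / tau_Ca`
#' with `F` the Faraday constant, `dpt = 0.1` um the shell depth and
#' `[Ca]_inf = 100` nM. An inward (negative) calcium current raises
#' cytosolic calcium.
#'
#' @param ca Cytosolic calcium, mM (`> 0`).
#' @param i_ca Total calcium current density, mA/cm2.
#' @param tau_ca Calcium decay time constant, ms.
#' @return Derivative, mM/ms.
#' @export
ca_derivative <- function(ca, i_ca, tau_ca) {
  stopifnot(all(ca > 0), tau_ca > 0)
  const <- stellate_constants()
  -10000 * i_ca / (36 * const$depth * const$Faraday) +
    (const$Ca_inf - ca) / tau_ca
}

#' Per-channel current densities at a model state
#'
#' @param model A `stellate_model`.
#' @param state A state vector as returned by [initial_state()] or
#'   [settle()].
#' @return Named vector of current densities (mA/cm2) for the nine active
#'   channels and the leak.
#' @export
channel_currents <- function(model, state) {
  stopifnot(inherits(model, "stellate_model"))
  .channel_currents_cpp(model$params, unclass(state),
                        model$ka_betah_as_printed) * 1e-3
}
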