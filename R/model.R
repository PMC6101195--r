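# Model assembly, initial/settled states, and the fixed-step simulator.

#' Build a single-compartment stellate cell model
#'
#' Assembles a parameter vector into a simulatable single-compartment
#' cylinder model (70 um diameter x 75 um length; lateral surface only, no
#' end caps). The leak reversal is fixed at -77 mV so that the passive model
#' (all active conductances zero) rests at -77 mV.
#'
#' @param params Named numeric vector of the 55 model parameters (canonical
#'   order of [parameter_space()]); defaults to the hand-tuned base model.
#' @param ka_betah_as_printed Use the literal printed form of the KA
#'   inactivation backward rate (see [gate_steady_state()]).
#' @return An object of class `stellate_model`: list with `params`, `area`
#'   (cm2), `ka_betah_as_printed`.
#' @export
#' @examples
#' m <- stellate_model()
#' m$area
stellate_model <- function(params = base_parameters(),
                           ka_betah_as_printed = FALSE) {
  p <- as_param_vector(params)
  if (any(!is.finite(p))) stop("parameters must be finite")
  gpars <- grep("^gbar_", names(p), value = TRUE)
  if (any(p[gpars] < 0)) {
    stop("negative conductance: ",
         paste(gpars[p[gpars] < 0], collapse = ", "))
  }
  if (p[["Rm"]] <= 0 || p[["Cm"]] <= 0) stop("Rm and Cm must be positive")
  const <- stellate_constants()
  area <- pi * (const$diameter * 1e-4) * (const$length * 1e-4)  # cm2
  structure(list(params = p, area = area,
                 ka_betah_as_printed = isTRUE(ka_betah_as_printed)),
            class = "stellate_model")
}

#' @export
print.stellate_model <- function(x, ...) {
  p <- x$params
  cat("Single-compartment stellate cell model\n")
  cat(sprintf("  membrane area: %.4g cm2 (70 um x 75 um cylinder)\n", x$area))
  cat(sprintf("  Rm = %.3g kOhm.cm2, Cm = %.3g uF/cm2, tau_Ca = %.3g ms\n",
              p[["Rm"]], p[["Cm"]], p[["tau_Ca"]]))
  g <- p[grep("^gbar_", names(p))]
  cat("  maximal conductances:\n")
  print(round(g, 4))
  invisible(x)
}

#' @export
summary.stellate_model <- function(object, ...) {
  print(object)
  s <- initial_state(object)
  cat("\nChannel current densities at the passive rest (-77 mV), mA/cm2:\n")
  print(signif(channel_currents(object, s), 3))
  invisible(object)
}

#' Initial state of a model
#'
#' State vector with the voltage-gated particles at their steady state for
#' the given voltage, the SK channel at its stationary distribution for the
#' given calcium, and calcium at its resting value.
#'
#' @param model A `stellate_model`.
#' @param V Initial membrane potential, mV (default: the passive rest).
#' @param ca Initial cytosolic calcium, mM.
#' @return Named state vector of length 22 (class `stellate_state`).
#' @export
initial_state <- function(model, V = stellate_constants()$E_leak,
                          ca = stellate_constants()$Ca_inf) {
  r <- .gate_rates_cpp(model$params, V, model$ka_betah_as_printed)
  sk <- sk_steady_state(ca)
  st <- c(V = V, setNames(as.numeric(r$inf), names(r$inf)),
          setNames(as.numeric(sk), paste0("SK_", names(sk))), Ca = ca)
  class(st) <- "stellate_state"
  st
}

#' Settle a model to its resting state
#'
#' Integrates the model with zero injected current (default 5 s) so that the
#' slow subthreshold conductances (HCN, SK, KM, calcium) reach their
#' steady-state interaction, and returns the full state. All measurement
#' protocols start from this settled state.
#'
#' @param model A `stellate_model`.
#' @param duration Settling time, ms.
#' @param dt Integration step, ms.
#' @param init Initial state; defaults to [initial_state()].
#' @return The settled state vector (class `stellate_state`).
#' @export
#' @examples
#' \donttest{
#' st <- settle(stellate_model(), duration = 1000)
#' }
settle <- function(model, duration = 5000, dt = 0.025, init = NULL) {
  tr <- simulate(model, stimulus = zero_stimulus(duration), dt = dt,
                 init = init, record_stride = max(1L, round(1 / dt)))
  if (attr(tr, "diverged")) {
    stop(sprintf("model diverged during settling at t = %.3f ms",
                 attr(tr, "t_diverged")))
  }
  st <- attr(tr, "state")
  class(st) <- "stellate_state"
  st
}

#' Simulate a model under a current-clamp stimulus
#'
#' Fixed-step integration (default step 25 us): exponential Euler for the 14
#' gating particles (exact for the per-step linear gate ODE), forward Euler
#' for voltage, calcium and the SK occupancies. Deterministic given (model,
#' initial state, stimulus, dt).
#'
#' @param object A `stellate_model`.
#' @param nsim,seed Unused (present for the [stats::simulate()] generic).
#' @param stimulus A stimulus object (see [step_stimulus()],
#'   [chirp_stimulus()], [gwn_stimulus()], [zero_stimulus()]) or a numeric
#'   vector of injected current samples (pA, one per integration step).
#' @param dt Integration step, ms.
#' @param init Initial state vector; defaults to [initial_state()] (passive
#'   rest). Use [settle()] first for measurement protocols.
#' @param record_stride Record every `record_stride`-th step (1 = every
#'   step).
#' @param record_ca,record_currents Also record calcium / per-channel current
#'   densities.
#' @param t0 Absolute time (ms) assigned to the first sample of the trace.
#' @param ... Unused.
#' @return A `stellate_trace`: data frame with columns `t` (ms), `V` (mV),
#'   `I` (pA), optionally `Ca` (mM), with attributes `dt` (integration
#'   step), `dt_record`, `state` (final state), `diverged`, `t_diverged`,
#'   and optionally `currents` (matrix, mA/cm2).
#' @export
#' @examples
#' \donttest{
#' m <- stellate_model()
#' tr <- simulate(m, stimulus = step_stimulus(-200, 1000), dt = 0.05)
#' }
simulate.stellate_model <- function(object, nsim = 1, seed = NULL,
                                    stimulus, dt = 0.025, init = NULL,
                                    record_stride = 1L, record_ca = FALSE,
                                    record_currents = FALSE, t0 = 0, ...) {
  if (is.null(init)) init <- initial_state(object)
  I <- if (is.numeric(stimulus)) stimulus else sample_stimulus(stimulus, dt)
  inj_scale <- 1e-6 / object$area  # pA -> uA/cm2
  out <- .simulate_cpp(object$params, as.numeric(init), I, dt, inj_scale,
                       as.integer(record_stride), record_ca, record_currents,
                       object$ka_betah_as_printed)
  n <- as.integer(out$n_recorded)
  idx <- seq_len(n)
  rec <- (idx - 1L) * record_stride
  tr <- data.frame(t = t0 + rec * dt, V = out$V[idx], I = I[rec + 1L])
  if (record_ca) tr$Ca <- out$Ca[idx]
  st <- out$state
  names(st) <- names(initial_state(object))
  structure(tr,
            class = c("stellate_trace", "data.frame"),
            dt = dt, dt_record = dt * record_stride, state = st,
            diverged = out$diverged, t_diverged = out$t_diverged,
            currents = if (record_currents) out$currents[idx, , drop = FALSE])
}

#' @export
print.stellate_trace <- function(x, ...) {
  cat(sprintf(
    "Membrane potential trace: %d samples, %.4g ms at %.4g ms resolution\n",
    nrow(x), nrow(x) * attr(x, "dt_record"), attr(x, "dt_record")))
  if (isTRUE(attr(x, "diverged"))) {
    cat(sprintf("  DIVERGED at t = %.3f ms\n", attr(x, "t_diverged")))
  }
  cat(sprintf("  V range: [%.2f, %.2f] mV\n", min(x$V), max(x$V)))
  invisible(x)
}

#' @export
plot.stellate_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$t / 1000, x$V, type = "l", xlab = "time (s)", ylab = "V (mV)", ...)
  plot(x$t / 1000, x$I, type = "l", xlab = "time (s)", ylab = "I (pA)", ...)
  invisible(x)
}

# Build a trace object from raw samples (used by the synthetic generators).
trace_from_samples <- function(V, dt_record, t0 = 0, I = NULL) {
  tr <- data.frame(t = t0 + (seq_along(V) - 1) * dt_record, V = V,
                   I = if (is.null(I)) 0 else I)
  structure(tr, class = c("stellate_trace", "data.frame"),
            dt = dt_record, dt_record = dt_record, state = NULL,
            diverged = FALSE, t_diverged = NA_real_)
}
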