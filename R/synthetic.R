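# Synthetic ground-truth traces. These emulate simulator output with known
# measurement values (flat rest, biexponential sag, sinusoidal oscillations,
# spike trains) so every measurement operation is testable independently of
# the ODE solver.

#' Synthetic ground-truth voltage traces
#'
#' Builds voltage traces whose measurement-relevant features are known
#' exactly from their construction parameters:
#'
#' * `kind = "flat"`: constant `level` (optionally plus Gaussian noise of SD
#'   `noise_sd`).
#' * `kind = "sag"`: baseline, then a hyperpolarizing step response rising
#'   exponentially to the peak deflection `v_peak` and relaxing
#'   exponentially to the steady-state deflection `v_ss`; ground-truth sag
#'   ratio is `v_ss / v_peak`.
#' * `kind = "mpo"`: sinusoid of frequency `freq` (Hz) and peak-to-peak
#'   amplitude `amp_pp` on `level`; ground truth `f_MPO = freq`,
#'   `V_MPO = amp_pp`.
#' * `kind = "spikes"`: baseline with triangular action potentials (2 ms
#'   base width, peak `peak`) at the given `spike_times`.
#'
#' @param kind Trace kind.
#' @param duration Trace duration, ms.
#' @param dt Sampling interval, ms.
#' @param t0 Absolute time of the first sample, ms.
#' @param level Baseline membrane potential, mV.
#' @param noise_sd Gaussian noise SD, mV (flat only).
#' @param seed Seed for the noise draws.
#' @param onset,step_duration Sag step timing, ms.
#' @param v_peak,v_ss Peak and steady-state deflections, mV (signed).
#' @param tau_rise,tau_settle Exponential time constants of the sag shape,
#'   ms.
#' @param freq Oscillation frequency, Hz.
#' @param amp_pp Peak-to-peak oscillation amplitude, mV.
#' @param spike_times Spike times, ms (absolute).
#' @param peak Spike peak voltage, mV.
#' @return A `stellate_trace`.
#' @export
#' @examples
#' tr <- synthetic_trace("mpo", duration = 3000, freq = 8, amp_pp = 4)
#' mpo_measurements(tr$V, attr(tr, "dt_record"))$f_MPO
synthetic_trace <- function(kind = c("flat", "sag", "mpo", "spikes"),
                            duration = 6000, dt = 0.25, t0 = 0,
                            level = -62, noise_sd = 0, seed = 1,
                            onset = 100, step_duration = 1000,
                            v_peak = -20, v_ss = -10, tau_rise = 30,
                            tau_settle = 120,
                            freq = 8, amp_pp = 4,
                            spike_times = NULL, peak = 20) {
  kind <- match.arg(kind)
  if (duration <= 0 || dt <= 0) stop("duration and dt must be positive")
  t <- seq(0, duration - dt, by = dt)
  V <- switch(kind,
    flat = {
      v <- rep(level, length(t))
      if (noise_sd > 0) {
        old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
        on.exit(if (!is.null(old))
          assign(".Random.seed", old, envir = globalenv()))
        set.seed(seed)
        v <- v + rnorm(length(t), 0, noise_sd)
      }
      v
    },
    sag = {
      v <- rep(level, length(t))
      instep <- t >= onset & t <= onset + step_duration
      ts <- t[instep] - onset
      # exponential approach to v_peak, then exponential relaxation to v_ss;
      # the transition sample is pinned to v_peak so the extreme deflection
      # equals v_peak exactly
      t_pk <- 5 * tau_rise
      d <- ifelse(ts <= t_pk,
                  v_peak * (1 - exp(-ts / tau_rise)) / (1 - exp(-t_pk / tau_rise)),
                  v_ss + (v_peak - v_ss) * exp(-(ts - t_pk) / tau_settle))
      v[instep] <- level + d
      v
    },
    mpo = level + (amp_pp / 2) * sin(2 * pi * freq * t / 1000),
    spikes = {
      v <- rep(level, length(t))
      for (ts in spike_times) {
        sel <- abs(t - ts) <= 1
        v[sel] <- pmax(v[sel], peak - (peak - level) * abs(t[sel] - ts))
      }
      v
    })
  trace_from_samples(V, dt_record = dt, t0 = t0)
}

#' @rdname synthetic_trace
#' @param spec A list with element `kind` plus the construction parameters
#'   for that kind, passed on to [synthetic_trace()].
#' @export
make_synthetic_trace <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$kind))
  do.call(synthetic_trace, spec)
}
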