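# The ten intrinsic measurements and their protocols. Pure trace-level
# operations (measure_rmp, measure_sag, spike detection, spectra) are
# separated from protocol drivers (measure_rin, measure_impedance, mpo_scan,
# measure_all) so each measurement can be tested on synthetic ground-truth
# traces independently of the integrator.

#' Detect action potentials in a voltage trace
#'
#' A spike is an upward crossing of the threshold (-20 mV) with a 1-ms
#' refractory lockout. -20 mV separates the subthreshold oscillation regime
#' (peak-to-peak < ~25 mV around perithreshold voltages) from full action
#' potentials (> ~60 mV amplitudes).
#'
#' @param trace A `stellate_trace` (or anything with `t` and `V` columns).
#' @param threshold Crossing threshold, mV.
#' @param refractory Lockout after a detected spike, ms.
#' @param window Optional `c(t_min, t_max)` restriction (ms, absolute).
#' @return Numeric vector of spike times (ms).
#' @export
detect_spikes <- function(trace, threshold = -20, refractory = 1,
                          window = NULL) {
  t <- trace$t
  V <- trace$V
  if (!is.null(window)) {
    sel <- t >= window[1] & t <= window[2]
    t <- t[sel]
    V <- V[sel]
  }
  n <- length(V)
  if (n < 2L) return(numeric(0))
  up <- which(V[-1] >= threshold & V[-n] < threshold) + 1L
  if (!length(up)) return(numeric(0))
  times <- t[up]
  keep <- c(TRUE, diff(times) > refractory)
  # enforce lockout sequentially (diff-based pruning is sufficient here
  # because removing a spike only increases the gap to the next one)
  times[keep]
}

#' @rdname detect_spikes
#' @return `count_spikes()`: the number of detected spikes.
#' @export
count_spikes <- function(trace, threshold = -20, refractory = 1,
                         window = NULL) {
  length(detect_spikes(trace, threshold, refractory, window))
}

#' Resting membrane potential and its stability
#'
#' Mean and standard deviation of the membrane potential over the 5-6 s
#' zero-current window (after the 5-s settling period). The SD criterion
#' (< 0.01 mV) certifies both steady-state attainment and the absence of
#' membrane potential oscillations at rest.
#'
#' @param trace A voltage trace covering the window.
#' @param window `c(t_min, t_max)` in ms (absolute trace time).
#' @return List with `V_RMP` (mV) and `V_SD` (mV).
#' @export
measure_rmp <- function(trace, window = c(5000, 6000)) {
  sel <- trace$t >= window[1] & trace$t <= window[2]
  if (sum(sel) < 2L) stop("trace does not cover the measurement window")
  list(V_RMP = mean(trace$V[sel]), V_SD = sd(trace$V[sel]))
}

#' Sag ratio from a hyperpolarizing step response
#'
#' Ratio of the steady-state membrane potential deflection to the peak
#' deflection, both relative to the pre-step baseline, for a hyperpolarizing
#' step (protocol: -200 pA for 1000 ms). The peak is the signed extreme
#' deflection within the step window; steady state is the mean over the last
#' `ss_window` ms of the step.
#'
#' @param trace Voltage trace containing the step and a pre-step baseline.
#' @param onset Step onset, ms (absolute trace time).
#' @param duration Step duration, ms.
#' @param baseline_window,ss_window Averaging windows, ms.
#' @return List with `Sag`, `V_peak`, `V_SS` (deflections, mV), `baseline`.
#' @export
measure_sag <- function(trace, onset, duration = 1000, baseline_window = 10,
                        ss_window = 10) {
  pre <- trace$t >= onset - baseline_window & trace$t < onset
  if (!any(pre)) stop("no pre-step baseline in trace")
  baseline <- mean(trace$V[pre])
  instep <- trace$t >= onset & trace$t <= onset + duration
  defl <- trace$V[instep] - baseline
  v_peak <- defl[which.max(abs(defl))]
  if (abs(v_peak) < 1e-9) stop("no membrane potential deflection")
  ss <- trace$t > onset + duration - ss_window & trace$t <= onset + duration
  v_ss <- mean(trace$V[ss] - baseline)
  list(Sag = v_ss / v_peak, V_peak = v_peak, V_SS = v_ss,
       baseline = baseline)
}

#' Input resistance from a family of subthreshold step responses
#'
#' `rin_fit()` is the pure fit: the least-squares slope of steady-state
#' voltage deflection against injected current (mV/pA scaled to MOhm).
#' `measure_rin()` runs the protocol: 1000-ms steps from -100 to +100 pA in
#' steps of 20 pA from the settled state, steady state read as the mean of
#' the final 10 ms.
#'
#' @param I_pA Injected currents, pA.
#' @param dV_mV Steady-state voltage deflections, mV.
#' @return `rin_fit()`: slope in MOhm. `measure_rin()`: list with `R_in`
#'   (MOhm), the per-sweep deflections, and `spiked` (TRUE if any sweep
#'   contained a spike; such sweeps contaminate the linear fit).
#' @export
rin_fit <- function(I_pA, dV_mV) {
  unname(coef(lm(dV_mV ~ I_pA))[2] * 1000)
}

#' @rdname rin_fit
#' @param model A `stellate_model`.
#' @param state Settled state (see [settle()]).
#' @param dt Integration step, ms.
#' @param currents Step amplitudes, pA.
#' @param duration Step duration, ms.
#' @export
measure_rin <- function(model, state, dt = 0.025,
                        currents = seq(-100, 100, by = 20),
                        duration = 1000) {
  v0 <- state[["V"]]
  stride <- max(1L, round(0.25 / dt))
  dV <- numeric(length(currents))
  spiked <- FALSE
  for (i in seq_along(currents)) {
    tr <- simulate(model, stimulus = step_stimulus(currents[i], duration),
                   dt = dt, init = state, record_stride = stride)
    if (attr(tr, "diverged")) return(list(R_in = NA_real_, spiked = TRUE,
                                          currents = currents, dV = dV))
    if (count_spikes(tr) > 0) spiked <- TRUE
    ss <- tr$t > duration - 10 & tr$t <= duration
    dV[i] <- mean(tr$V[ss]) - v0
  }
  list(R_in = rin_fit(currents, dV), currents = currents, dV = dV,
       spiked = spiked)
}

#' Impedance profile from a chirp response
#'
#' `impedance_profile()` computes frequency-dependent impedance as the ratio
#' of the Fourier transform of the voltage response to that of the chirp
#' stimulus, restricted to the analysis band. `impedance_metrics()` derives
#' the resonance frequency `f_R` (argmax of the amplitude profile), the
#' resonance strength `Q_R` (amplitude at `f_R` over the amplitude at the
#' bin nearest 0.5 Hz), and the total inductive phase `Phi_L` (area under
#' the positive region of the phase profile, rad Hz).
#'
#' @param trace Voltage trace of the chirp response (with the stimulus in
#'   column `I`).
#' @param band Analysis band, Hz.
#' @return `impedance_profile()`: data frame `f` (Hz), `Zmag` (MOhm),
#'   `phase` (rad), class `impedance_profile`.
#' @export
impedance_profile <- function(trace, band = c(0.5, 15)) {
  dtr <- attr(trace, "dt_record")
  n <- nrow(trace)
  Z <- fft(trace$V - mean(trace$V)) / fft(trace$I - mean(trace$I))
  f <- (seq_len(n) - 1) / (n * dtr / 1000)
  sel <- f >= band[1] & f <= band[2]
  # mV/pA = GOhm; report MOhm
  out <- data.frame(f = f[sel], Zmag = 1000 * Mod(Z[sel]),
                    phase = Arg(Z[sel]))
  class(out) <- c("impedance_profile", "data.frame")
  out
}

#' @rdname impedance_profile
#' @param profile An `impedance_profile`.
#' @param q_ref Reference frequency for `Q_R`, Hz.
#' @return `impedance_metrics()`: list `f_R`, `Q_R`, `Phi_L`.
#' @export
impedance_metrics <- function(profile, q_ref = 0.5) {
  i_max <- which.max(profile$Zmag)
  i_ref <- which.min(abs(profile$f - q_ref))
  phi_pos <- pmax(profile$phase, 0)
  n <- nrow(profile)
  phi_l <- sum(diff(profile$f) * (phi_pos[-1] + phi_pos[-n]) / 2)
  list(f_R = profile$f[i_max], Q_R = profile$Zmag[i_max] / profile$Zmag[i_ref],
       Phi_L = phi_l)
}

#' @rdname impedance_profile
#' @param model A `stellate_model`.
#' @param state Settled state.
#' @param dt Integration step, ms.
#' @param chirp Chirp stimulus (default: 0-15 Hz in 15 s, 40 pA
#'   peak-to-peak).
#' @param tail Zero-current tail appended after the chirp, ms.
#' @return `measure_impedance()`: list `f_R`, `Q_R`, `Phi_L`, `profile`,
#'   `spiked`. If the model spikes during the chirp the metrics are `NA`
#'   and `spiked` is `TRUE`.
#' @export
measure_impedance <- function(model, state, dt = 0.025,
                              chirp = chirp_stimulus(), tail = 1000) {
  stride <- max(1L, round(0.25 / dt))
  # a zero-current tail lets the response decay inside the record, removing
  # the end-discontinuity leakage from the transform ratio
  I <- c(sample_stimulus(chirp, dt), numeric(round(tail / dt)))
  tr <- simulate(model, stimulus = I, dt = dt, init = state,
                 record_stride = stride)
  if (attr(tr, "diverged") || count_spikes(tr) > 0) {
    return(list(f_R = NA_real_, Q_R = NA_real_, Phi_L = NA_real_,
                profile = NULL, spiked = TRUE))
  }
  prof <- impedance_profile(tr)
  c(impedance_metrics(prof), list(profile = prof, spiked = FALSE))
}

#' Oscillation measurements of one depolarized voltage segment
#'
#' Rectangular-window discrete Fourier transform of the mean-subtracted
#' segment; the peak of the one-sided amplitude spectrum (DC excluded)
#' defines the oscillation frequency. Segments whose spectral peak amplitude
#' is below `min_amplitude` are reported as non-oscillatory (`f_MPO = 0`).
#'
#' @param V Voltage samples of the analysis segment, mV.
#' @param dt_record Sampling interval of `V`, ms.
#' @param f_max Upper frequency limit of the peak search, Hz.
#' @param min_amplitude Minimum spectral peak amplitude (mV) to count as an
#'   oscillation.
#' @return List `f_MPO` (Hz; 0 if non-oscillatory), `amplitude` (spectral
#'   peak amplitude, mV), `V_avg` (mV), `V_MPO` (peak-to-peak, mV).
#' @export
mpo_measurements <- function(V, dt_record, f_max = 25, min_amplitude = 0.01) {
  n <- length(V)
  A <- 2 * Mod(fft(V - mean(V))) / n
  f <- (seq_len(n) - 1) / (n * dt_record / 1000)
  sel <- f > 0 & f <= f_max
  i <- which.max(A[sel])
  fpk <- f[sel][i]
  apk <- A[sel][i]
  list(f_MPO = if (apk >= min_amplitude) fpk else 0, amplitude = apk,
       V_avg = mean(V), V_MPO = max(V) - min(V))
}

#' Depolarization scan for membrane potential oscillations
#'
#' Injects 5-s depolarizing steps spanning 100-300 pA in 10-pA increments
#' from the settled state and analyzes the last 3 s of each response
#' (transform of the mean-subtracted segment; peak magnitude frequency =
#' `f_MPO`). The perithreshold oscillation frequency `f_osc` is the `f_MPO`
#' of the largest current whose analyzed 3-s window contains zero spikes
#' (onset transients before the analysis window do not disqualify a sweep),
#' provided that sweep has a nonzero spectral peak; otherwise `f_osc` is
#' `NA` (no robust perithreshold oscillations -- a validation failure).
#'
#' @param model A `stellate_model`.
#' @param state Settled state.
#' @param dt Integration step, ms.
#' @param currents Step amplitudes, pA.
#' @param duration Step duration, ms.
#' @param analysis_window Length of the trailing analysis segment, ms.
#' @return List with `sweeps` (data frame: `I`, `f_MPO`, `amplitude`,
#'   `V_avg`, `V_MPO`, `n_spikes`) and `f_osc` (Hz or `NA`).
#' @export
mpo_scan <- function(model, state, dt = 0.025,
                     currents = seq(100, 300, by = 10), duration = 5000,
                     analysis_window = 3000) {
  stride <- max(1L, round(0.25 / dt))
  rows <- vector("list", length(currents))
  for (i in seq_along(currents)) {
    tr <- simulate(model, stimulus = step_stimulus(currents[i], duration),
                   dt = dt, init = state, record_stride = stride)
    if (attr(tr, "diverged")) {
      rows[[i]] <- data.frame(I = currents[i], f_MPO = NA_real_,
                              amplitude = NA_real_, V_avg = NA_real_,
                              V_MPO = NA_real_, n_spikes = NA_integer_)
      next
    }
    seg <- tr$V[tr$t > duration - analysis_window]
    m <- mpo_measurements(seg, attr(tr, "dt_record"))
    rows[[i]] <- data.frame(I = currents[i], f_MPO = m$f_MPO,
                            amplitude = m$amplitude, V_avg = m$V_avg,
                            V_MPO = m$V_MPO,
                            n_spikes = count_spikes(tr,
                              window = c(duration - analysis_window,
                                         duration)),
                            n_spikes_total = count_spikes(tr))
  }
  sweeps <- do.call(rbind, rows)
  sub <- which(sweeps$n_spikes == 0)
  f_osc <- NA_real_
  if (length(sub)) {
    peri <- sub[which.max(sweeps$I[sub])]
    if (!is.na(sweeps$f_MPO[peri]) && sweeps$f_MPO[peri] > 0) {
      f_osc <- sweeps$f_MPO[peri]
    }
  }
  list(sweeps = sweeps, f_osc = f_osc)
}

#' Spike amplitude
#'
#' Difference between the peak voltage of the first action potential of a
#' sweep (protocol: the 400-pA step) and the resting membrane potential.
#'
#' @param trace Voltage trace containing at least one spike.
#' @param v_rmp Resting membrane potential, mV.
#' @param peak_window Window after the threshold crossing within which the
#'   peak is read, ms.
#' @return Spike amplitude, mV.
#' @export
measure_vap <- function(trace, v_rmp, peak_window = 5) {
  sp <- detect_spikes(trace)
  if (!length(sp)) stop("no action potential in trace")
  sel <- trace$t >= sp[1] & trace$t <= sp[1] + peak_window
  max(trace$V[sel]) - v_rmp
}

MEASUREMENT_NAMES <- c("V_RMP", "V_SD", "Sag", "R_in", "Q_R", "f_R", "f_osc",
                       "N_100", "N_400", "V_AP")

# Map each validation measurement to the protocol stage that produces it.
STAGE_MEASUREMENTS <- list(
  rmp = c("V_RMP", "V_SD"), sag = "Sag", rin = "R_in",
  chirp = c("Q_R", "f_R"), steps = c("N_100", "N_400", "V_AP"),
  mpo = "f_osc")

#' Run all measurement protocols on a model
#'
#' Settles the model (5 s), measures the resting potential over the next
#' second, then runs the remaining protocols from the settled state in the
#' order sag, input resistance, chirp, 100/400-pA steps, depolarization
#' scan. With `bounds` and `short_circuit = TRUE`, a protocol stage whose
#' measurements already violate the bounds aborts the remaining (more
#' expensive) stages; unevaluated measurements are `NA` and the abort stage
#' is recorded. Validity decisions are unaffected because a failed criterion
#' already invalidates the model.
#'
#' @param model A `stellate_model`.
#' @param dt Integration step, ms.
#' @param protocols Which protocol stages to run.
#' @param bounds Optional [validation_bounds()] enabling short-circuiting.
#' @param short_circuit Abort after the first stage that fails `bounds`.
#' @param settle_duration Settling time, ms.
#' @return A `measurement_set`: list with the ten validation measurements,
#'   `Phi_L`, the `mpo` sweep table, `flags` (character), and `aborted_at`
#'   (stage name or `NA`).
#' @export
#' @examples
#' \donttest{
#' ms <- measure_all(stellate_model(), dt = 0.1,
#'                   protocols = c("rmp", "sag"))
#' }
measure_all <- function(model, dt = 0.025,
                        protocols = c("rmp", "sag", "rin", "chirp", "steps",
                                      "mpo"),
                        bounds = NULL, short_circuit = !is.null(bounds),
                        settle_duration = 5000) {
  protocols <- match.arg(protocols, several.ok = TRUE)
  m <- as.list(setNames(rep(NA_real_, length(MEASUREMENT_NAMES)),
                        MEASUREMENT_NAMES))
  m$Phi_L <- NA_real_
  m$mpo <- NULL
  flags <- character(0)
  aborted <- NA_character_

  fails <- function(names) {
    if (is.null(bounds) || !short_circuit) return(FALSE)
    for (nm in intersect(names, bounds$name)) {
      b <- bounds[bounds$name == nm, ]
      v <- m[[nm]]
      if (is.na(v) || (!is.na(b$lower) && v < b$lower) ||
          (!is.na(b$upper) && v > b$upper)) {
        return(TRUE)
      }
    }
    FALSE
  }
  finish <- function() {
    structure(c(m, list(flags = flags, aborted_at = aborted)),
              class = "measurement_set", dt = dt)
  }

  st <- tryCatch(settle(model, settle_duration, dt), error = function(e) e)
  if (inherits(st, "error")) {
    flags <- c(flags, "diverged")
    aborted <- "settle"
    return(finish())
  }

  # resting potential: sixth second at zero current
  rmp_tr <- simulate(model, stimulus = zero_stimulus(1000), dt = dt,
                     init = st, record_stride = max(1L, round(0.1 / dt)),
                     t0 = settle_duration)
  r <- measure_rmp(rmp_tr, window = settle_duration + c(0, 1000))
  m$V_RMP <- r$V_RMP
  m$V_SD <- r$V_SD
  if (count_spikes(rmp_tr) > 0) flags <- c(flags, "spontaneous_firing")
  st6 <- attr(rmp_tr, "state")
  class(st6) <- "stellate_state"
  if (("spontaneous_firing" %in% flags && short_circuit) ||
      fails(c("V_RMP", "V_SD"))) {
    aborted <- "rmp"
    return(finish())
  }

  if ("sag" %in% protocols) {
    tr <- simulate(model,
                   stimulus = step_stimulus(-200, 1000, onset = 100,
                                            tail = 100),
                   dt = dt, init = st6,
                   record_stride = max(1L, round(0.25 / dt)))
    m$Sag <- if (attr(tr, "diverged")) NA_real_ else
      measure_sag(tr, onset = 100)$Sag
    if (fails("Sag")) {
      aborted <- "sag"
      return(finish())
    }
  }

  if ("rin" %in% protocols) {
    rin <- measure_rin(model, st6, dt)
    m$R_in <- rin$R_in
    if (rin$spiked) flags <- c(flags, "rin_spike")
    if (fails("R_in")) {
      aborted <- "rin"
      return(finish())
    }
  }

  if ("chirp" %in% protocols) {
    imp <- measure_impedance(model, st6, dt)
    m$Q_R <- imp$Q_R
    m$f_R <- imp$f_R
    m$Phi_L <- imp$Phi_L
    if (imp$spiked) flags <- c(flags, "chirp_spike")
    if (fails(c("Q_R", "f_R"))) {
      aborted <- "chirp"
      return(finish())
    }
  }

  if ("steps" %in% protocols) {
    tr100 <- simulate(model, stimulus = step_stimulus(100, 500), dt = dt,
                      init = st6)
    m$N_100 <- if (attr(tr100, "diverged")) NA_real_ else count_spikes(tr100)
    tr400 <- simulate(model, stimulus = step_stimulus(400, 500), dt = dt,
                      init = st6)
    if (attr(tr400, "diverged")) {
      m$N_400 <- NA_real_
    } else {
      m$N_400 <- count_spikes(tr400)
      if (m$N_400 > 0) m$V_AP <- measure_vap(tr400, m$V_RMP)
      if (has_depolarization_block(tr400)) flags <- c(flags, "depol_block")
    }
    if (fails(c("N_100", "N_400", "V_AP"))) {
      aborted <- "steps"
      return(finish())
    }
  }

  if ("mpo" %in% protocols) {
    mp <- mpo_scan(model, st6, dt)
    m$f_osc <- mp$f_osc
    m$mpo <- mp$sweeps
  }
  finish()
}

# Depolarization-induced block: after at least one spike, the voltage stays
# above -20 mV for more than 100 ms contiguously without spiking.
has_depolarization_block <- function(trace, threshold = -20,
                                     min_plateau = 100) {
  if (count_spikes(trace, threshold) == 0) return(FALSE)
  dtr <- attr(trace, "dt_record")
  above <- trace$V > threshold
  r <- rle(above)
  any(r$values & r$lengths * dtr > min_plateau)
}

#' @export
print.measurement_set <- function(x, ...) {
  cat("Intrinsic measurements:\n")
  v <- unlist(x[MEASUREMENT_NAMES])
  print(signif(v, 4))
  if (!is.null(x$Phi_L) && !is.na(x$Phi_L)) {
    cat(sprintf("Phi_L = %.4g rad Hz\n", x$Phi_L))
  }
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  if (!is.na(x$aborted_at)) cat("aborted at stage:", x$aborted_at, "\n")
  invisible(x)
}
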