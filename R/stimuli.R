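# Current-clamp stimulus constructors. A stimulus is a lightweight
# description; sample_stimulus() renders it to one current sample (pA) per
# integration step.

new_stimulus <- function(kind, duration, ...) {
  if (duration <= 0) stop("stimulus duration must be positive")
  structure(list(kind = kind, duration = duration, ...), class = "stimulus")
}

#' Current-clamp stimuli
#'
#' Constructors for the measurement protocols: zero current, rectangular
#' step, impedance chirp, and zero-mean Gaussian white noise.
#'
#' * `zero_stimulus(duration)`: no injected current.
#' * `step_stimulus(amplitude, duration, onset, tail)`: `amplitude` pA held
#'   for `duration` ms after `onset` ms of baseline, followed by `tail` ms of
#'   zero current.
#' * `chirp_stimulus()`: constant-amplitude sinusoid (default 40 pA
#'   peak-to-peak) whose frequency sweeps linearly from 0 to `f_max` Hz over
#'   `duration` ms; instantaneous frequency at time t is
#'   `f_max * t / duration`.
#' * `gwn_stimulus(sigma, duration, seed)`: zero-mean Gaussian white noise,
#'   one independent draw of SD `sigma` pA per integration step
#'   (piecewise-constant over a step), reproducible under `seed`.
#'
#' @param duration Stimulus duration, ms.
#' @param amplitude Step amplitude, pA.
#' @param onset Baseline before the step, ms.
#' @param tail Zero-current tail after the step, ms.
#' @param f_max Final chirp frequency, Hz.
#' @param amp_pp Chirp peak-to-peak amplitude, pA.
#' @param sigma Noise standard deviation, pA.
#' @param seed Integer seed for the noise draws.
#' @return A `stimulus` object.
#' @name stimuli
#' @export
zero_stimulus <- function(duration) {
  new_stimulus("zero", duration)
}

#' @rdname stimuli
#' @export
step_stimulus <- function(amplitude, duration, onset = 0, tail = 0) {
  new_stimulus("step", onset + duration + tail, amplitude = amplitude,
               onset = onset, step_duration = duration, tail = tail)
}

#' @rdname stimuli
#' @export
chirp_stimulus <- function(duration = 15000, f_max = 15, amp_pp = 40) {
  new_stimulus("chirp", duration, f_max = f_max, amp_pp = amp_pp)
}

#' @rdname stimuli
#' @export
gwn_stimulus <- function(sigma, duration, seed) {
  if (sigma < 0) stop("sigma must be nonnegative")
  new_stimulus("gwn", duration, sigma = sigma, seed = as.integer(seed))
}

#' Render a stimulus to per-step current samples
#'
#' @param stim A `stimulus`.
#' @param dt Integration step, ms.
#' @return Numeric vector of injected current samples (pA), one per step.
#' @export
sample_stimulus <- function(stim, dt) {
  stopifnot(inherits(stim, "stimulus"), dt > 0)
  n <- round(stim$duration / dt)
  switch(stim$kind,
    zero = numeric(n),
    step = {
      I <- numeric(n)
      i0 <- round(stim$onset / dt)
      i1 <- round((stim$onset + stim$step_duration) / dt)
      I[(i0 + 1):i1] <- stim$amplitude
      I
    },
    chirp = {
      t_s <- (seq_len(n) - 1) * dt / 1000  # s
      T_s <- stim$duration / 1000
      # phase of a linear 0 -> f_max sweep: 2 pi f_max t^2 / (2 T)
      (stim$amp_pp / 2) * sin(pi * stim$f_max * t_s^2 / T_s)
    },
    gwn = {
      old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
      set.seed(stim$seed)
      rnorm(n, 0, stim$sigma)
    },
    stop("unsupported stimulus kind: ", stim$kind)
  )
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf("<stimulus: %s, %.4g ms>\n", x$kind, x$duration))
  invisible(x)
}
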