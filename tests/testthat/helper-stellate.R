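# Shared fixtures, built in code and cached across tests within a run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

base_model_fx <- function() cached("base_model", stellate_model())

# Parameter vector with all active conductances zero (passive RC membrane).
passive_params <- function() {
  p <- base_parameters()
  p[grep("^gbar_", names(p))] <- 0
  p
}

passive_model_fx <- function() cached("passive_model",
                                      stellate_model(passive_params()))

settled_base_fx <- function(dt = 0.025) {
  cached(paste0("settled_base_", dt), settle(base_model_fx(), dt = dt))
}

# Full base-model measurement set at the reference step size.
base_measurements_fx <- function() {
  cached("base_measurements", measure_all(base_model_fx(), dt = 0.025))
}

# Analytic RC impedance magnitude (MOhm) and phase (rad) of the passive
# membrane: Z(f) = R / (1 + i 2 pi f R C).
rc_impedance <- function(f_hz, model = passive_model_fx()) {
  R <- model$params[["Rm"]] * 1000 / model$area    # Ohm
  C <- model$params[["Cm"]] * 1e-6 * model$area    # F
  z <- R / (1 + 1i * 2 * pi * f_hz * R * C)
  list(mag = Mod(z) / 1e6, phase = Arg(z))
}
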