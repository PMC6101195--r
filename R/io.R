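# Plain-text serialization helpers. Traces and populations are stored as
# CSV (with YAML metadata); channel definitions can be exported as a YAML
# audit document.

#' Write a trace to CSV
#'
#' Writes the recorded samples (time, voltage, stimulus, calcium if
#' recorded) with a YAML-ish comment header carrying the sampling metadata.
#'
#' @param trace A `stellate_trace`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_trace_csv <- function(trace, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt: %g ms, dt_record: %g ms, diverged: %s",
                     attr(trace, "dt"), attr(trace, "dt_record"),
                     attr(trace, "diverged")), con)
  write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(file)
}

#' Export the channel definitions as YAML
#'
#' Writes an auditable description of every gated conductance: gate names,
#' exponents, reversal/current formulation, and the per-gate parameters
#' (half-voltage, slope, time-constant scale factor) for a given parameter
#' vector.
#'
#' @param params Parameter vector (55); defaults to the base model.
#' @param file Output path, or `NULL` to return the list invisibly.
#' @return The channel-spec list (invisibly if written to file).
#' @export
export_channel_specs <- function(params = base_parameters(), file = NULL) {
  p <- as_param_vector(params)
  gate <- function(role, Vh, k, F_) {
    list(role = role, half_voltage_mV = unname(Vh), slope_mV = unname(k),
         tau_scale = unname(F_))
  }
  spec <- list(
    NaF = list(current = "ohmic", reversal_mV = 50, gates = "m^3 h",
               gbar = unname(p["gbar_NaF"]), gbar_unit = "mS/cm2",
               m = gate("activation", p["Vm_NaF"], p["km_NaF"], p["Fm_NaF"]),
               h = gate("inactivation", p["Vh_NaF"], p["kh_NaF"], p["Fh_NaF"])),
    KDR = list(current = "ohmic", reversal_mV = -90, gates = "n^4",
               gbar = unname(p["gbar_KDR"]), gbar_unit = "mS/cm2",
               n = gate("activation", p["Vn_KDR"], p["kn_KDR"], p["Fn_KDR"])),
    HCN = list(current = "ohmic", reversal_mV = -20,
               gates = "ms + ratio * mf (sigmoid powers -58.5 slow, -1.36 fast)",
               gbar_slow = unname(p["gbar_HCN"]), gbar_unit = "uS/cm2",
               fast_to_slow_ratio = unname(p["HCN_fs_ratio"]),
               mf = gate("activation", -p["Vmf_HCN"], p["kmf_HCN"],
                         p["Fmf_HCN"]),
               ms = gate("activation", -p["Vms_HCN"], p["kms_HCN"],
                         p["Fms_HCN"])),
    NaP = list(current = "ohmic", reversal_mV = 50, gates = "m h",
               gbar = unname(p["gbar_NaP"]), gbar_unit = "uS/cm2",
               m = gate("activation", -p["Vm_NaP"], p["km_NaP"], p["Fm_NaP"]),
               h = gate("inactivation", -p["Vh_NaP"], p["kh_NaP"],
                        p["Fh_NaP"])),
    KA = list(current = "ohmic", reversal_mV = -90, gates = "m h",
              gbar = unname(p["gbar_KA"]), gbar_unit = "uS/cm2",
              m = gate("activation", p["Vm_KA"], p["km_KA"], p["Fm_KA"]),
              h = gate("inactivation", p["Vh_KA"], p["kh_KA"], p["Fh_KA"])),
    HVA = list(current = "GHK", gates = "m^3 h",
               gbar = unname(p["gbar_HVA"]), gbar_unit = "mS/cm2",
               m = gate("activation", -p["Vm_HVA"], p["km_HVA"],
                        p["Fm_HVA"]),
               h = gate("inactivation", -p["Vh_HVA"], p["kh_HVA"],
                        p["Fh_HVA"])),
    LVA = list(current = "GHK", gates = "m^2 h s([Ca])",
               gbar = unname(p["gbar_LVA"]), gbar_unit = "uS/cm2",
               m = gate("activation", p["Vm_LVA"], p["km_LVA"], p["Fm_LVA"]),
               h = gate("inactivation", p["Vh_LVA"], p["kh_LVA"],
                        p["Fh_LVA"])),
    KM = list(current = "ohmic", reversal_mV = -90, gates = "m",
              gbar = unname(p["gbar_KM"]), gbar_unit = "mS/cm2",
              m = gate("activation", p["Vm_KM"], p["km_KM"], p["Fm_KM"])),
    SK = list(current = "ohmic", reversal_mV = -90,
              gates = "6-state Markov open fraction (O1 + O2)",
              gbar = unname(p["gbar_SK"]), gbar_unit = "uS/cm2",
              rates = as.list(stellate_constants()$sk_rates))
  )
  if (is.null(file)) return(invisible(spec))
  yaml::write_yaml(spec, file)
  invisible(spec)
}
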