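# Virtual knockout models: zero one channel's maximal conductance in each
# valid model, recompute the measurements, and quantify the change.

VKM_CHANNELS <- c(NaF = "gbar_NaF", KDR = "gbar_KDR", HCN = "gbar_HCN",
                  NaP = "gbar_NaP", KA = "gbar_KA", LVA = "gbar_LVA",
                  HVA = "gbar_HVA", KM = "gbar_KM", SK = "gbar_SK")

#' Virtual knockout of one channel
#'
#' Returns the parameter vector with the named channel's maximal conductance
#' set to zero; all other 54 parameters are untouched. Zeroing the HCN
#' conductance removes both its fast and slow components (the fast
#' conductance is defined as a ratio of the slow one).
#'
#' @param params Parameter vector (55).
#' @param channel One of `"NaF"`, `"KDR"`, `"HCN"`, `"NaP"`, `"KA"`,
#'   `"LVA"`, `"HVA"`, `"KM"`, `"SK"`.
#' @return The knocked-out parameter vector.
#' @export
#' @examples
#' p <- knockout(base_parameters(), "HCN")
#' p["gbar_HCN"]
knockout <- function(params, channel) {
  if (length(channel) != 1L || !channel %in% names(VKM_CHANNELS)) {
    stop("unknown channel: ", paste(channel, collapse = ", "),
         " (must be one of ", paste(names(VKM_CHANNELS), collapse = ", "),
         ")")
  }
  p <- as_param_vector(params)
  p[VKM_CHANNELS[[channel]]] <- 0
  p
}

# Percentage-change measurements; N_100 is reported as an absolute count
# change because its pre-knockout value is constrained to zero.
VKM_PERCENT <- c("V_RMP", "Sag", "R_in", "Q_R", "f_R", "f_osc", "N_400",
                 "V_AP")

#' Screen a population with a single-channel knockout
#'
#' For each model, knocks out the channel, re-runs the measurement
#' protocols, and records the change in each measurement: percentage change
#' relative to the pre-knockout value for the continuous measurements, and
#' an absolute count change for `N_100`. Knockout models that fire
#' spontaneously at rest or enter depolarization-induced block during the
#' 400-pA step are excluded (their subthreshold measurements are not
#' interpretable) with the reason recorded.
#'
#' @param params Matrix of pre-knockout parameter vectors (models x 55), or
#'   a single vector.
#' @param channel Channel to knock out (see [knockout()]).
#' @param base_measurements Data frame of the pre-knockout measurements (one
#'   row per model, columns as in a population's `measurements`). If `NULL`
#'   they are recomputed.
#' @param dt Integration step, ms.
#' @param protocols Protocol stages to run on the knockouts (restrict to
#'   speed up targeted contrasts; the resting-potential stage always runs).
#' @return A `vkm_result`: data frame with one row per model (`model`,
#'   `channel`, `excluded`, `reason`, post-knockout measurements `post_*`,
#'   and changes `d_*`).
#' @export
vkm_screen <- function(params, channel, base_measurements = NULL,
                       dt = 0.025,
                       protocols = c("rmp", "sag", "rin", "chirp", "steps",
                                     "mpo")) {
  if (is.null(dim(params))) params <- matrix(params, nrow = 1,
                                             dimnames = list(NULL, names(params)))
  n <- nrow(params)
  if (is.null(base_measurements)) {
    base_measurements <- do.call(rbind, lapply(seq_len(n), function(i) {
      measurement_row(measure_all(stellate_model(params[i, ]), dt = dt,
                                  protocols = protocols))
    }))
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ko <- measure_all(stellate_model(knockout(params[i, ], channel)),
                      dt = dt, protocols = protocols)
    excl <- if ("diverged" %in% ko$flags) "diverged"
      else if ("spontaneous_firing" %in% ko$flags) "spontaneous-firing"
      else if ("depol_block" %in% ko$flags) "depolarization-block"
      else ""
    row <- data.frame(model = i, channel = channel,
                      excluded = excl != "", reason = excl)
    for (nm in MEASUREMENT_NAMES) {
      row[[paste0("post_", nm)]] <- ko[[nm]]
    }
    if (excl == "") {
      for (nm in VKM_PERCENT) {
        pre <- base_measurements[[nm]][i]
        row[[paste0("d_", nm)]] <-
          if (is.na(pre) || pre == 0) NA_real_ else
            100 * (ko[[nm]] - pre) / pre
      }
      row$d_N_100 <- ko$N_100 - base_measurements$N_100[i]
    } else {
      for (nm in VKM_PERCENT) row[[paste0("d_", nm)]] <- NA_real_
      row$d_N_100 <- NA_real_
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("vkm_result", "data.frame")
  out
}

#' Test knockout-induced changes against a no-change null
#'
#' Two-sided nonparametric test of whether the distribution of
#' post-knockout changes differs from zero: a one-sample Wilcoxon
#' signed-rank test against 0 (default), or a Wilcoxon rank sum test of the
#' changes against an equal-length zero vector.
#'
#' @param changes Numeric vector of per-model changes (NAs dropped).
#' @param variant `"signed-rank"` (one-sample against 0) or
#'   `"rank-sum-zero"`.
#' @param min_n Minimum number of non-missing changes.
#' @return The two-sided p value.
#' @export
vkm_test_changes <- function(changes, variant = c("signed-rank",
                                                  "rank-sum-zero"),
                             min_n = 6) {
  variant <- match.arg(variant)
  x <- changes[!is.na(changes)]
  if (length(x) < min_n) stop("too few non-excluded results")
  if (all(x == 0)) return(1)
  suppressWarnings(switch(variant,
    "signed-rank" = wilcox.test(x, mu = 0)$p.value,
    "rank-sum-zero" = wilcox.test(x, rep(0, length(x)))$p.value))
}
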