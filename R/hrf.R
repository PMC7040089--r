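#' Canonical single-gamma hemodynamic response kernel
#'
#' Gamma-density kernel `h(t) ~ t^(a-1) exp(-t/b)` with shape `a = 6` and
#' scale chosen so the kernel peaks at `peak_s` seconds.  Two
#' normalisations: `"peak"` (max = 1; used to inject activation so the
#' plateau of a long block equals the stated amplitude times the kernel
#' area ratio) and `"area"` (sum = 1; used when convolving a boxcar so a
#' sustained block converges to the boxcar amplitude).
#'
#' @param sampling_period_s sampling period, s
#' @param peak_s time-to-peak, s
#' @param duration_s kernel support, s
#' @param normalize `"area"` or `"peak"`
#' @return numeric kernel sampled at the frame rate
#' @export
hrf_kernel <- function(sampling_period_s = 0.3, peak_s = 7,
                       duration_s = 30, normalize = c("area", "peak")) {
  normalize <- match.arg(normalize)
  shape <- 6
  scale <- peak_s / (shape - 1)
  t <- seq(0, duration_s, by = sampling_period_s)
  h <- t^(shape - 1) * exp(-t / scale)
  if (normalize == "area") h / sum(h) else h / max(h)
}

#' Theoretical activation model for a block protocol
#'
#' Box function over the answer blocks convolved with the unit-area
#' hemodynamic kernel: the noiseless shape of a sustained "yes" response,
#' with plateau equal to the boxcar amplitude for long blocks.
#'
#' @param protocol a `protocol_design`
#' @param peak_s hemodynamic kernel time-to-peak, s
#' @param amplitude boxcar amplitude (plateau target)
#' @return numeric series over the run's frames
#' @export
activation_model <- function(protocol, peak_s = 7, amplitude = 1) {
  box <- as.numeric(answer_block_mask(protocol)) * amplitude
  h <- hrf_kernel(protocol$frame_period_s, peak_s, normalize = "area")
  as.numeric(stats::filter(c(rep(0, length(h)), box), h,
                           method = "convolution", sides = 1))[-seq_along(h)]
}

#' Noiseless hemodynamic concentration time courses for one run
#'
#' "no" runs are identically zero; "yes" runs are the activation model
#' scaled to the participant's oxy- and deoxyhemoglobin plateau amplitudes.
#'
#' @param protocol a `protocol_design`
#' @param truth `"yes"` or `"no"`
#' @param profile a [participant_profile()]
#' @return list with `delta_hbo2` and `delta_hb` (uM, per frame)
#' @export
hemodynamic_timecourse <- function(protocol, truth, profile) {
  truth <- match.arg(truth, c("yes", "no"))
  n <- protocol$frames_per_run
  if (truth == "no" || !profile$responder ||
      (profile$amp_hbo2 == 0 && profile$amp_hb == 0))
    return(list(delta_hbo2 = numeric(n), delta_hb = numeric(n)))
  shape <- activation_model(protocol, profile$hrf_peak_s)
  list(delta_hbo2 = profile$amp_hbo2 * shape,
       delta_hb = profile$amp_hb * shape)
}
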