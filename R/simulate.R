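#' Acquisition configuration
#'
#' Describes the time-correlated single-photon-counting acquisition being
#' emulated: an 80-MHz pulse train (12.5-ns window) histogrammed into 1024
#' bins, one frame per channel and wavelength every 300 ms, a Gaussian
#' instrument response, and the expected photon count per frame.
#'
#' @param n_bins DTOF bins per frame
#' @param window_ps histogram span, ps
#' @param counts_per_frame expected detected photons per frame
#' @param irf_fwhm_ps instrument-response full width at half maximum, ps
#' @param wavelengths the two laser wavelengths, nm
#' @param n_channels detection channels
#' @return an `acquisition_config`
#' @export
acquisition_config <- function(n_bins = 1024, window_ps = 12500,
                               counts_per_frame = 1e5, irf_fwhm_ps = 400,
                               wavelengths = c(760, 830), n_channels = 4) {
  structure(list(n_bins = n_bins, window_ps = window_ps,
                 counts_per_frame = counts_per_frame,
                 irf_fwhm_ps = irf_fwhm_ps, wavelengths = wavelengths,
                 n_channels = n_channels,
                 bin_edges_ps = seq(0, window_ps, length.out = n_bins + 1)),
            class = "acquisition_config")
}

#' Virtual participant profile
#'
#' Hemodynamic and noise characteristics of one simulated participant.
#' Non-responders (participants whose imagery elicits no detectable
#' hemodynamic response) have both amplitudes forced to zero.
#'
#' @param id participant label
#' @param responder logical; FALSE forces zero activation amplitudes
#' @param amp_hbo2 oxyhemoglobin plateau amplitude during imagery, uM (>= 0)
#' @param amp_hb deoxyhemoglobin plateau amplitude, uM (<= 0)
#' @param hrf_peak_s hemodynamic response time-to-peak, s
#' @param noise_scales multiplicative scales for the noise generators:
#'   `drift`, `cardiac`, `mayer`, `cerebral_lfo`, `motion_rate` (events per
#'   minute), `motion_amp`
#' @return a `participant_profile`
#' @export
participant_profile <- function(id, responder = TRUE, amp_hbo2 = 0.5,
                                amp_hb = -0.15, hrf_peak_s = 7,
                                noise_scales = list()) {
  if (!responder) { amp_hbo2 <- 0; amp_hb <- 0 }
  if (amp_hbo2 < 0) stop("amp_hbo2 must be >= 0")
  if (amp_hb > 0) stop("amp_hb must be <= 0")
  ns <- utils::modifyList(list(drift = 1, cardiac = 1, mayer = 1,
                               cerebral_lfo = 1, motion_rate = 0.3,
                               motion_amp = 1), noise_scales)
  structure(list(id = id, responder = responder, amp_hbo2 = amp_hbo2,
                 amp_hb = amp_hb, hrf_peak_s = hrf_peak_s,
                 noise_scales = ns),
            class = "participant_profile")
}

# Baseline noise amplitudes (scaled by the profile's noise_scales).
# Anchors: scalp hemoglobin oscillations of a few tenths of a uM (cardiac
# ~1.1 Hz, Mayer waves ~0.1 Hz) plus slow drift; cerebral spontaneous
# low-frequency oscillations an order of magnitude below the activation
# amplitude, which is what makes some "no" runs look weakly active.
NOISE_BASE <- list(
  scalp_cardiac_uM = 0.4, cardiac_hz = 1.1,
  scalp_mayer_uM = 0.4, mayer_hz = 0.10,
  scalp_drift_uM = 0.4,       # linear drift SD over a full run
  scalp_walk_uM = 0.02,       # random-walk step SD per frame
  brain_lfo_uM = 0.10, lfo_hz = 0.09,
  brain_walk_uM = 0.005,
  hb_ratio = -0.25,           # Hb change accompanying systemic HbO2 change
  motion_shift_sd_bins = 8, motion_dur_mean_frames = 4,
  motion_amp_sd = 0.15)

# Systemic + intrinsic nuisance concentration series for one channel.
# Returns uM time courses for the scalp compartment and the brain
# compartment (additive to activation).
nuisance_timecourses <- function(protocol, profile) {
  ns <- profile$noise_scales
  tt <- frame_times_s(protocol)
  n <- length(tt)
  b <- NOISE_BASE
  scalp <- ns$cardiac * b$scalp_cardiac_uM *
      sin(2 * pi * b$cardiac_hz * stats::runif(1, 0.9, 1.1) * tt +
          stats::runif(1, 0, 2 * pi)) +
    ns$mayer * b$scalp_mayer_uM *
      sin(2 * pi * b$mayer_hz * stats::runif(1, 0.8, 1.2) * tt +
          stats::runif(1, 0, 2 * pi)) +
    ns$drift * (b$scalp_drift_uM * stats::rnorm(1) * tt / max(tt) +
                b$scalp_walk_uM * cumsum(stats::rnorm(n)))
  brain <- ns$cerebral_lfo * b$brain_lfo_uM *
      sin(2 * pi * b$lfo_hz * stats::runif(1, 0.8, 1.2) * tt +
          stats::runif(1, 0, 2 * pi)) +
    ns$drift * b$brain_walk_uM * cumsum(stats::rnorm(n))
  list(scalp_hbo2 = scalp, brain_hbo2 = brain)
}

# Motion events as a data frame of (frame, duration, shift_bins, amp_factor)
draw_motion_events <- function(protocol, profile) {
  b <- NOISE_BASE
  rate <- profile$noise_scales$motion_rate
  n_ev <- stats::rpois(1, rate * protocol$total_run_s / 60)
  if (n_ev == 0)
    return(data.frame(frame = integer(0), dur = integer(0),
                      shift = integer(0), amp = numeric(0)))
  data.frame(
    frame = sample.int(protocol$frames_per_run, n_ev),
    dur = 1L + stats::rgeom(n_ev, 1 / b$motion_dur_mean_frames),
    shift = as.integer(round(stats::rnorm(n_ev,
      sd = b$motion_shift_sd_bins * profile$noise_scales$motion_amp))),
    amp = exp(stats::rnorm(n_ev, sd = b$motion_amp_sd *
                             profile$noise_scales$motion_amp)))
}

#' Precompute the baseline DTOF template for the run simulator
#'
#' Bins a photon record set onto the acquisition grid at the medium's
#' baseline absorption, scales it to the configured counts per frame, and
#' prepares the per-bin mean pathlengths (for fast first-order absorption
#' perturbation) and the FFT of the Gaussian instrument response.
#'
#' @param records a `photon_records` object
#' @param acq an [acquisition_config()]
#' @return a `run_template`
#' @export
dtof_run_template <- function(records, acq = acquisition_config()) {
  tmpl <- bin_photon_records(records, acq$bin_edges_ps)
  medium <- records$meta$medium
  scale <- acq$counts_per_frame / sum(tmpl$counts)
  B <- tmpl$counts * scale
  Lb <- rowSums(tmpl$layer_path_means[, medium$brain_layers, drop = FALSE])
  Ls <- tmpl$layer_path_means[, 1]
  # circularly wrapped symmetric Gaussian IRF on the bin grid
  dt_bin <- acq$window_ps / acq$n_bins
  sigma <- acq$irf_fwhm_ps / (2 * sqrt(2 * log(2))) / dt_bin
  r <- ceiling(4 * sigma)
  k <- exp(-0.5 * ((-r):r / sigma)^2)
  k <- k / sum(k)
  kw <- numeric(acq$n_bins)
  kw[1:(r + 1)] <- k[(r + 1):(2 * r + 1)]
  kw[(acq$n_bins - r + 1):acq$n_bins] <- k[1:r]
  structure(list(B = B, Lb = Lb, Ls = Ls, irf_fft = stats::fft(kw),
                 acq = acq, medium = medium,
                 medium_hash = records$meta$medium_hash,
                 mc_seed = records$meta$seed),
            class = "run_template")
}

#' Simulate one question run of DTOF time series
#'
#' Generates, for every channel and wavelength, the full frames x bins DTOF
#' count series of one run: brain activation (truth-dependent boxcar
#' convolved with the hemodynamic kernel, mapped to per-wavelength brain
#' absorption changes through the Beer-Lambert forward model), superficial
#' systemic oscillations and drift in the scalp layer, first-order DTOF
#' perturbation of the Monte-Carlo baseline template, Gaussian instrument
#' response, motion spikes (time-origin shift plus amplitude transient) and
#' Poisson counting noise.
#'
#' @param protocol a `protocol_design`
#' @param profile a [participant_profile()]
#' @param truth `"yes"` or `"no"`
#' @param template a [dtof_run_template()]
#' @param table an [extinction_table()]
#' @param seed RNG seed for this run
#' @param noise logical; FALSE disables all noise sources (expected counts
#'   are returned, useful for closed-loop validation)
#' @return a `dtof_run`: `counts[[channel]][[wavelength]]` (frames x bins
#'   matrices), `bin_edges_ps`, `truth`, `profile`, `seed`
#' @export
simulate_run <- function(protocol, profile, truth, template,
                         table = extinction_table(), seed, noise = TRUE) {
  if (missing(seed)) stop("an explicit seed is required")
  acq <- template$acq
  set.seed(seed)
  act <- hemodynamic_timecourse(protocol, truth, profile)
  nf <- protocol$frames_per_run
  counts <- vector("list", acq$n_channels)
  for (ch in seq_len(acq$n_channels)) {
    if (noise) {
      nui <- nuisance_timecourses(protocol, profile)
      events <- draw_motion_events(protocol, profile)
    } else {
      nui <- list(scalp_hbo2 = numeric(nf), brain_hbo2 = numeric(nf))
      events <- NULL
    }
    brain_mua <- mua_from_hb(act$delta_hbo2 + nui$brain_hbo2,
                             act$delta_hb + NOISE_BASE$hb_ratio * nui$brain_hbo2,
                             table)
    scalp_mua <- mua_from_hb(nui$scalp_hbo2,
                             NOISE_BASE$hb_ratio * nui$scalp_hbo2, table)
    per_wl <- vector("list", length(acq$wavelengths))
    for (wi in seq_along(acq$wavelengths)) {
      E <- template$B * exp(-(template$Lb %o% brain_mua[, wi] +
                              template$Ls %o% scalp_mua[, wi]))
      # instrument response: circular convolution along the bin axis
      E <- Re(stats::mvfft(stats::mvfft(E) * template$irf_fft,
                           inverse = TRUE)) / acq$n_bins
      E[E < 0] <- 0
      if (!is.null(events) && nrow(events) > 0)
        E <- apply_motion_events(E, events)
      M <- if (noise) {
        matrix(stats::rpois(length(E), E), nrow(E), ncol(E))
      } else E
      per_wl[[wi]] <- t(M)
    }
    names(per_wl) <- as.character(acq$wavelengths)
    counts[[ch]] <- per_wl
  }
  structure(list(counts = counts, bin_edges_ps = acq$bin_edges_ps,
                 protocol = protocol, truth = truth,
                 participant = profile$id, seed = seed,
                 wavelengths = acq$wavelengths),
            class = "dtof_run")
}

# Shift (time origin) and scale (amplitude) the affected frames.
apply_motion_events <- function(E, events) {
  nb <- nrow(E); nf <- ncol(E)
  for (i in seq_len(nrow(events))) {
    fr <- events$frame[i]:min(nf, events$frame[i] + events$dur[i] - 1L)
    s <- events$shift[i]
    block <- E[, fr, drop = FALSE] * events$amp[i]
    if (s > 0) {
      block <- rbind(matrix(0, s, length(fr)), block[1:(nb - s), , drop = FALSE])
    } else if (s < 0) {
      block <- rbind(block[(-s + 1):nb, , drop = FALSE], matrix(0, -s, length(fr)))
    }
    E[, fr] <- block
  }
  E
}

#' Simulate a full synthetic study cohort
#'
#' Draws participant profiles (activation amplitudes, hemodynamic peak
#' latency, noise scales, responder status), assigns each participant a
#' randomised yes/no answer scheme over the questions, and fixes one RNG
#' seed per run.  Runs are realised lazily with [realize_run()] so a full
#' DTOF cohort never has to be held in memory at once.
#'
#' @param n_participants cohort size (>= 2; default 18, a typical analysed
#'   cohort after exclusions)
#' @param n_questions questions per participant
#' @param non_responder_frac probability that a participant shows no
#'   detectable imagery response (default 0.12, the middle of the 10-15%
#'   range reported for healthy adults)
#' @param master_seed master RNG seed; everything else derives from it
#' @param mode `"dtof"` for full physics (requires `template`) or
#'   `"concentration"` for the fast concentration-level generator used when
#'   only decoding statistics matter
#' @param template a [dtof_run_template()] (dtof mode)
#' @param protocol a `protocol_design`
#' @param table an [extinction_table()]
#' @param n_yes number of "yes" answers per participant
#' @return a `cohort_plan` with `manifest` (one row per run: participant,
#'   question_index, truth, seed, amplitudes), `profiles`, and the shared
#'   configuration
#' @export
simulate_cohort <- function(n_participants = 18, n_questions = 4,
                            non_responder_frac = 0.12, master_seed,
                            mode = c("dtof", "concentration"),
                            template = NULL, protocol = build_protocol(),
                            table = extinction_table(), n_yes = 2) {
  mode <- match.arg(mode)
  if (n_participants < 2) stop("need at least 2 participants for cross-validation")
  if (non_responder_frac < 0 || non_responder_frac >= 1)
    stop("non_responder_frac must be in [0, 1)")
  if (mode == "dtof" && is.null(template))
    stop("dtof mode requires a run template (see dtof_run_template)")
  if (missing(master_seed)) stop("an explicit master_seed is required")
  set.seed(master_seed)
  profiles <- list()
  rows <- list()
  for (p in seq_len(n_participants)) {
    responder <- stats::runif(1) >= non_responder_frac
    amp <- stats::rnorm(1, 0.5, 0.15) # plateau, truncated at 0.1 uM
    while (amp < 0.1) amp <- stats::rnorm(1, 0.5, 0.15)
    peak <- stats::rnorm(1, 7, 0.5)
    scales <- exp(stats::rnorm(4, 0, 0.2)) # fixed draw order: part of the contract
    prof <- participant_profile(
      id = sprintf("P%02d", p), responder = responder,
      amp_hbo2 = amp, amp_hb = -0.3 * amp, hrf_peak_s = peak,
      noise_scales = list(drift = scales[1], cardiac = scales[2],
                          mayer = scales[3], cerebral_lfo = scales[4]))
    profiles[[p]] <- prof
    truth <- sample(c(rep("yes", n_yes), rep("no", n_questions - n_yes)))
    rows[[p]] <- data.frame(participant = prof$id,
                            question_index = seq_len(n_questions),
                            truth = truth,
                            seed = sample.int(.Machine$integer.max - 1,
                                              n_questions),
                            responder = responder,
                            amp_hbo2 = prof$amp_hbo2,
                            amp_hb = prof$amp_hb)
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  structure(list(manifest = manifest, profiles = profiles,
                 protocol = protocol, mode = mode, template = template,
                 table = table, master_seed = master_seed,
                 non_responder_frac = non_responder_frac),
            class = "cohort_plan")
}

#' @export
print.cohort_plan <- function(x, ...) {
  cat(sprintf("cohort_plan (%s): %d participants x %d questions, %d non-responders, master seed %s\n",
              x$mode, length(x$profiles), max(x$manifest$question_index),
              sum(!vapply(x$profiles, `[[`, logical(1), "responder")),
              format(x$master_seed)))
  invisible(x)
}

#' Realise one run of a cohort plan
#'
#' @param plan a `cohort_plan`
#' @param i manifest row index
#' @param noise logical; FALSE disables the noise generators
#' @return a `dtof_run` (dtof mode) or a `concentration_run` (list of
#'   per-channel uM series with truth metadata)
#' @export
realize_run <- function(plan, i, noise = TRUE) {
  row <- plan$manifest[i, ]
  prof <- plan$profiles[[match(row$participant,
                               vapply(plan$profiles, `[[`, character(1), "id"))]]
  if (plan$mode == "dtof")
    return(simulate_run(plan$protocol, prof, row$truth, plan$template,
                        plan$table, seed = row$seed, noise = noise))
  simulate_concentration_run(plan$protocol, prof, row$truth,
                             seed = row$seed, noise = noise)
}

# Concentration-level generator: the same activation and physiological
# noise model expressed directly in uM, plus white measurement noise at the
# level the photon-counting chain would produce after moment inversion
# (~0.5 uM per frame at 1e5 counts/frame).  Used for decoding-statistics
# studies where the optics adds cost but no information.
simulate_concentration_run <- function(protocol, profile, truth, seed,
                                       noise = TRUE, n_channels = 4,
                                       white_sd_uM = 0.55) {
  set.seed(seed)
  act <- hemodynamic_timecourse(protocol, truth, profile)
  nf <- protocol$frames_per_run
  hbo2 <- vector("list", n_channels)
  hb <- vector("list", n_channels)
  for (ch in seq_len(n_channels)) {
    if (noise) {
      nui <- nuisance_timecourses(protocol, profile)
      w <- stats::rnorm(nf, sd = white_sd_uM)
      # scalp signals reach the concentration estimate strongly attenuated:
      # the mean time-of-flight is depth-weighted (~3% effective leakage)
      leak <- 0.03
      hbo2[[ch]] <- act$delta_hbo2 + nui$brain_hbo2 + leak * nui$scalp_hbo2 + w
      hb[[ch]] <- act$delta_hb + NOISE_BASE$hb_ratio * nui$brain_hbo2 +
        leak * NOISE_BASE$hb_ratio * nui$scalp_hbo2 +
        stats::rnorm(nf, sd = white_sd_uM / 2)
    } else {
      hbo2[[ch]] <- act$delta_hbo2
      hb[[ch]] <- act$delta_hb
    }
  }
  structure(list(hbo2_by_channel = hbo2, hb_by_channel = hb,
                 truth = truth, participant = profile$id, seed = seed,
                 protocol = protocol),
            class = "concentration_run")
}
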