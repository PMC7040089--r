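make_irf_fft <- function(acq) {
  dt_bin <- acq$window_ps / acq$n_bins
  sigma <- acq$irf_fwhm_ps / (2 * sqrt(2 * log(2))) / dt_bin
  r <- ceiling(4 * sigma)
  k <- exp(-0.5 * ((-r):r / sigma)^2)
  k <- k / sum(k)
  kw <- numeric(acq$n_bins)
  kw[1:(r + 1)] <- k[(r + 1):(2 * r + 1)]
  kw[(acq$n_bins - r + 1):acq$n_bins] <- k[1:r]
  stats::fft(kw)
}

irf_convolve <- function(x, irf_fft) {
  Re(stats::fft(stats::fft(x) * irf_fft, inverse = TRUE)) / length(x)
}

#' Acquisition-matched sensitivity factors
#'
#' The raw-moment sensitivity factors of [compute_mtsf()] describe the
#' untruncated arrival-time distribution.  The measured mean time-of-flight,
#' however, is computed on an instrument-response-convolved DTOF truncated
#' at fractions of its peak, which attenuates the late (most
#' brain-sensitive) photons.  For an unbiased inversion the sensitivity
#' factor must be derived from the same windowed moment the pipeline
#' measures; this function does so by pushing the baseline and a
#' brain-perturbed photon ensemble through the identical binning,
#' instrument-response and truncation chain and finite-differencing the
#' windowed mean.
#'
#' @details
#' Because the truncation thresholds are relative to the frame's peak, the
#' window edges themselves move (in expectation, linearly) with the
#' perturbation; a fixed-window derivative therefore underestimates the
#' measured response.  The factor is obtained as a calibration slope: the
#' brain absorption is stepped over the physiological operating range
#' (`delta_grid`), each perturbed ensemble is pushed through the identical
#' measurement operator (binning, instrument response, per-frame
#' truncation, windowed mean), and the through-origin least-squares slope
#' of windowed mean versus absorption step is returned.
#'
#' @param records a `photon_records` object
#' @param acq an [acquisition_config()]
#' @param delta_grid absorption steps (mm^-1) spanning the operating range
#'   of the calibration, applied to all brain layers
#' @param rise_frac,fall_frac truncation thresholds of the processing chain
#' @return list with `mtsf` (ps mm, acquisition-matched brain sensitivity),
#'   `mtsf_moments` (raw-moment counterpart), `calibration` (data frame of
#'   the points)
#' @export
windowed_mtsf <- function(records, acq = acquisition_config(),
                          delta_grid = seq(1e-5, 1.2e-4, by = 1e-5),
                          rise_frac = 0.10, fall_frac = 0.01) {
  medium <- records$meta$medium
  K <- length(medium$layers)
  irf <- make_irf_fft(acq)
  centers <- bin_centers(acq$bin_edges_ps)
  wtof <- function(d) {
    dbrain <- numeric(K)
    dbrain[medium$brain_layers] <- d
    tmpl <- bin_photon_records(records, acq$bin_edges_ps,
                               mu_a = medium_mua(medium) + dbrain)
    cnt <- irf_convolve(tmpl$counts, irf)
    cnt[cnt < 0] <- 0
    # same interpolated-window moment the per-frame pipeline computes
    mtof_matrix(matrix(cnt, 1), centers, rise_frac, fall_frac)$t_mean
  }
  m0 <- wtof(0)
  dm <- vapply(delta_grid, wtof, numeric(1)) - m0
  slope <- sum(dm * delta_grid) / sum(delta_grid^2)
  raw <- compute_mtsf(records, medium)
  list(mtsf = slope, mtsf_moments = raw$mtsf,
       mtsf_moments_se = raw$mtsf_se,
       calibration = data.frame(delta_mua = delta_grid, delta_t = dm),
       brain_layers = medium$brain_layers)
}

#' Per-wavelength sensitivity factors for the inversion
#'
#' Builds the wavelength -> MTSF map used by the concentration inversion.
#' With a single record set the same layered model (and hence the same
#' factor) serves both wavelengths; passing one record set per wavelength
#' gives wavelength-specific factors.
#'
#' Because the truncation thresholds are peak-relative, the measured
#' response is calibrated over an absorption operating range, and that
#' range is wavelength-specific: the same oxy-up / deoxy-down hemodynamic
#' pattern produces roughly six-fold smaller absorption changes at 760 nm
#' than at 830 nm.  Each wavelength's calibration grid is therefore derived
#' from a reference concentration span (`hbo2_span_uM`, with the
#' accompanying deoxy change `hb_ratio` times it) mapped through the
#' extinction coefficients.
#'
#' @param records a `photon_records`, or a named list of them keyed by
#'   wavelength
#' @param acq an [acquisition_config()]
#' @param method `"windowed"` (acquisition-matched, the pipeline default)
#'   or `"moments"` (raw untruncated moments)
#' @param table an [extinction_table()] (windowed calibration ranges)
#' @param hbo2_span_uM upper end of the oxyhemoglobin operating range, uM
#' @param hb_ratio deoxy/oxy amplitude ratio of the reference pattern
#' @return a named numeric vector of MTSF values (ps mm) keyed by wavelength
#' @export
pipeline_sensitivity <- function(records, acq = acquisition_config(),
                                 method = c("windowed", "moments"),
                                 table = extinction_table(),
                                 hbo2_span_uM = 0.6, hb_ratio = -0.3) {
  method <- match.arg(method)
  wl <- as.character(acq$wavelengths)
  mua_max <- drop(mua_from_hb(hbo2_span_uM, hb_ratio * hbo2_span_uM, table))
  one <- function(rec, w) {
    if (method == "moments") return(compute_mtsf(rec)$mtsf)
    grid <- seq(mua_max[[w]] / 12, mua_max[[w]], length.out = 12)
    windowed_mtsf(rec, acq, delta_grid = grid)$mtsf
  }
  if (inherits(records, "photon_records"))
    return(vapply(stats::setNames(wl, wl), function(w) one(records, w),
                  numeric(1)))
  if (!all(wl %in% names(records))) stop("record sets missing for a wavelength")
  vapply(stats::setNames(wl, wl), function(w) one(records[[w]], w), numeric(1))
}

#' Process one simulated (or recorded) DTOF run to concentrations
#'
#' The published processing chain: per channel and wavelength, windowed
#' mean time-of-flight per frame referenced to the baseline period; motion
#' detection and spline correction; cosine-basis detrending; hemodynamic
#' smoothing; moment inversion to absorption changes; two-wavelength
#' Beer-Lambert inversion to oxy-/deoxyhemoglobin.
#'
#' @param run a `dtof_run`
#' @param mtsf named per-wavelength MTSF vector from
#'   [pipeline_sensitivity()]
#' @param table an [extinction_table()]
#' @param rise_frac,fall_frac DTOF truncation thresholds
#' @param clean logical; FALSE skips motion correction, detrending and
#'   smoothing (used by closed-loop validation)
#' @return a `concentration_run` (per-channel uM series plus metadata)
#' @export
process_run <- function(run, mtsf, table = extinction_table(),
                        rise_frac = 0.10, fall_frac = 0.01, clean = TRUE) {
  protocol <- run$protocol
  wl <- as.character(run$wavelengths)
  hbo2 <- list(); hb <- list()
  for (ch in seq_along(run$counts)) {
    mua <- list()
    for (w in wl) {
      ser <- delta_mtof_series(run$counts[[ch]][[w]], run$bin_edges_ps,
                               baseline_frames = protocol$frames_baseline,
                               rise_frac = rise_frac, fall_frac = fall_frac,
                               frame_period_s = protocol$frame_period_s)
      dtv <- ser$delta_t
      if (any(ser$bad)) # bad frames carried as NA; bridge before filtering
        dtv <- stats::approx(which(!ser$bad), dtv[!ser$bad],
                             xout = seq_along(dtv), rule = 2)$y
      if (clean)
        dtv <- clean_timecourse(dtv, protocol$frame_period_s)$values
      mua[[w]] <- delta_mua_from_mtof(dtv, mtsf[[w]])
    }
    hbt <- hb_concentrations(mua, table)
    hbo2[[ch]] <- hbt$delta_hbo2
    hb[[ch]] <- hbt$delta_hb
  }
  structure(list(hbo2_by_channel = hbo2, hb_by_channel = hb,
                 truth = run$truth, participant = run$participant,
                 seed = run$seed, protocol = protocol),
            class = "concentration_run")
}

#' Process every run of a cohort plan
#'
#' Realises each run of the plan in turn (raw DTOF data are generated,
#' processed and discarded run by run), producing the per-run concentration
#' time courses that epoch averaging and decoding work from.
#'
#' @param plan a `cohort_plan`
#' @param mtsf per-wavelength MTSF vector (dtof mode only)
#' @param table an [extinction_table()]
#' @param clean see [process_run()]
#' @param verbose print progress
#' @return a `cohort_runs`: `runs` (list of `concentration_run`),
#'   `protocol`, `manifest`
#' @export
process_cohort <- function(plan, mtsf = NULL, table = extinction_table(),
                           clean = TRUE, verbose = FALSE) {
  n <- nrow(plan$manifest)
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    r <- realize_run(plan, i)
    if (inherits(r, "dtof_run")) {
      if (is.null(mtsf)) stop("dtof mode requires sensitivity factors")
      r <- process_run(r, mtsf, table, clean = clean)
    } else if (clean) {
      r$hbo2_by_channel <- lapply(r$hbo2_by_channel, function(x)
        clean_timecourse(x, plan$protocol$frame_period_s)$values)
      r$hb_by_channel <- lapply(r$hb_by_channel, function(x)
        clean_timecourse(x, plan$protocol$frame_period_s)$values)
    }
    r$question_index <- plan$manifest$question_index[i]
    runs[[i]] <- r
    if (verbose && i %% 8 == 0)
      message(sprintf("processed run %d/%d", i, n))
  }
  structure(list(runs = runs, protocol = plan$protocol,
                 manifest = plan$manifest),
            class = "cohort_runs")
}

#' Feature table from processed runs
#'
#' Block-averages each run's oxyhemoglobin channels over the first
#' `n_cycles` cycles and extracts the four features, yielding the question
#' records that the classifiers consume.
#'
#' @param runs a `cohort_runs`
#' @param protocol the `protocol_design`
#' @param n_cycles cycles to include in the epochs
#' @param peak_s hemodynamic kernel time-to-peak for the model feature
#' @param slope_window_s slope window, s
#' @return data frame: participant, question_index, SM, SS, CNR, r, truth
#' @export
features_from_runs <- function(runs, protocol = runs$protocol,
                               n_cycles = protocol$n_cycles, peak_s = 7,
                               slope_window_s = 16) {
  rows <- lapply(runs$runs, function(r) {
    ep <- average_epochs(r$hbo2_by_channel, protocol, n_cycles)
    f <- extract_features(ep, protocol, peak_s, slope_window_s)
    data.frame(participant = r$participant,
               question_index = r$question_index,
               SM = f$SM, SS = f$SS, CNR = f$CNR, r = f$r,
               truth = r$truth)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read the feature table as TSV
#'
#' @param features data frame from [features_from_runs()]
#' @param path file path
#' @export
write_features_tsv <- function(features, path) {
  utils::write.table(features, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_features_tsv
#' @export
read_features_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Persist a cohort dataset to disk
#'
#' Realises every run of the plan and writes it (counts and bin edges) to
#' `dir`, one file per run, together with the ground-truth manifest and the
#' plan metadata.  [read_dataset()] restores a lossless copy.
#'
#' @param plan a `cohort_plan`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(plan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(plan$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  meta <- list(mode = plan$mode, master_seed = plan$master_seed,
               non_responder_frac = plan$non_responder_frac,
               layout_version = 1)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  for (i in seq_len(nrow(plan$manifest)))
    saveRDS(realize_run(plan, i), file.path(dir, sprintf("run_%03d.rds", i)))
  saveRDS(plan[setdiff(names(plan), "template")],
          file.path(dir, "plan.rds"))
  invisible(dir)
}

#' @rdname write_dataset
#' @param dir dataset directory written by [write_dataset()]
#' @return list with `manifest`, `meta` and `runs`
#' @export
read_dataset <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("not a dataset directory: missing meta.json")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$layout_version)) stop("dataset missing layout_version")
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop("dataset missing manifest.json")
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^run_\\d+\\.rds$", full.names = TRUE))
  list(manifest = manifest, meta = meta, runs = lapply(files, readRDS))
}

pipeline_defaults <- function() {
  list(
    optics = list(n_photons = 1e6, mc_seed = 7001,
                  separation_mm = 30, detector_halfwidth_mm = 2),
    acquisition = list(n_bins = 1024, window_ps = 12500,
                       counts_per_frame = 1e5, irf_fwhm_ps = 400,
                       n_channels = 4),
    protocol = list(baseline_s = 30, n_cycles = 5, answer_s = 30,
                    rest_s = 30, frame_period_ms = 300),
    cohort = list(n_participants = 18, n_questions = 4,
                  non_responder_frac = 0.12, master_seed = 2024,
                  mode = "dtof"),
    decoding = list(cycles = FALSE))
}

#' Read a pipeline configuration
#'
#' Reads a YAML configuration, validates it against the known schema
#' (unknown keys are rejected) and merges it over the defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults
#' @return nested configuration list
#' @export
read_config <- function(path = NULL) {
  cfg <- pipeline_defaults()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (sec in names(user)) {
    if (!sec %in% names(cfg))
      stop(sprintf("unknown config section '%s'", sec))
    for (key in names(user[[sec]])) {
      if (!key %in% names(cfg[[sec]]))
        stop(sprintf("unknown config key '%s.%s'", sec, key))
      cfg[[sec]][[key]] <- user[[sec]][[key]]
    }
  }
  cfg
}

#' Run the full simulation-to-decoding pipeline
#'
#' Executes the complete chain: Monte-Carlo sensitivity factors, synthetic
#' cohort generation, DTOF processing and cleaning, concentration
#' inversion, epoch features, and LDA/SVM subset-search decoding.
#'
#' @param config configuration list from [read_config()] (or `NULL` for
#'   defaults)
#' @param output_dir if given, the report JSON and feature TSV are written
#'   here
#' @param verbose print stage progress
#' @return a `pipeline_report` list: `sensitivity`, `features`, `svm`,
#'   `lda`, `per_question`, optional `cycles`, `config`, timings
#' @export
run_pipeline <- function(config = NULL, output_dir = NULL, verbose = TRUE) {
  if (is.null(config)) config <- pipeline_defaults()
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  stage_s <- list()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    stage_s[[name]] <<- t1 - t0
    t0 <<- t1
  }

  say("stage sensitivity: %g photon packets", config$optics$n_photons)
  acq <- do.call(acquisition_config, config$acquisition)
  geo <- geometry(config$optics$separation_mm,
                  config$optics$detector_halfwidth_mm)
  records <- run_photon_mc(layered_medium(), geo,
                           n_photons = config$optics$n_photons,
                           seed = config$optics$mc_seed,
                           t_max_ps = acq$window_ps)
  mtsf <- pipeline_sensitivity(records, acq)
  template <- dtof_run_template(records, acq)
  tick("sensitivity")

  say("stage simulate+process: %d participants", config$cohort$n_participants)
  protocol <- do.call(build_protocol, config$protocol)
  plan <- simulate_cohort(
    n_participants = config$cohort$n_participants,
    n_questions = config$cohort$n_questions,
    non_responder_frac = config$cohort$non_responder_frac,
    master_seed = config$cohort$master_seed,
    mode = config$cohort$mode, template = template, protocol = protocol)
  runs <- process_cohort(plan, mtsf, verbose = verbose)
  tick("process")

  say("stage features")
  features <- features_from_runs(runs)
  tick("features")

  say("stage classify")
  svm_rep <- subset_search(features, "svm")
  lda_rep <- subset_search(features, "lda")
  pq <- per_question_accuracy(features, svm_rep$best_subset, "svm",
                              n_positions = config$cohort$n_questions)
  cycles <- if (isTRUE(config$decoding$cycles))
    cycles_curve(runs, protocol, "svm") else NULL
  tick("classify")

  report <- list(sensitivity = list(mtsf = mtsf,
                                    n_detected = n_detected(records),
                                    mc_seed = config$optics$mc_seed),
                 features = features, svm = svm_rep, lda = lda_rep,
                 per_question = pq, cycles = cycles,
                 manifest = plan$manifest,
                 config = config, stage_seconds = stage_s)
  class(report) <- "pipeline_report"
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_features_tsv(features, file.path(output_dir, "features.tsv"))
    jsonlite::write_json(
      list(mtsf = as.list(mtsf),
           svm = svm_rep$table, lda = lda_rep$table,
           svm_best = list(subset = svm_rep$best_subset,
                           accuracy = svm_rep$best_accuracy,
                           sensitivity = svm_rep$best_result$sensitivity,
                           specificity = svm_rep$best_result$specificity),
           lda_best = list(subset = lda_rep$best_subset,
                           accuracy = lda_rep$best_accuracy),
           per_question = pq,
           master_seed = config$cohort$master_seed,
           stage_seconds = as.list(stage_s)),
      file.path(output_dir, "results.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat(sprintf("  MTSF: %s ps mm\n",
              paste(sprintf("%s nm: %.0f", names(x$sensitivity$mtsf),
                            x$sensitivity$mtsf), collapse = ", ")))
  cat(sprintf("  SVM best: %s at %.1f%% (sens %.1f%%, spec %.1f%%)\n",
              paste(x$svm$best_subset, collapse = "+"), x$svm$best_accuracy,
              x$svm$best_result$sensitivity, x$svm$best_result$specificity))
  cat(sprintf("  LDA best: %s at %.1f%%\n",
              paste(x$lda$best_subset, collapse = "+"), x$lda$best_accuracy))
  cat(sprintf("  per-question accuracy: %s\n",
              paste(sprintf("%.0f%%", x$per_question), collapse = ", ")))
  invisible(x)
}
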