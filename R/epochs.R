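#' Block-averaged response epoch
#'
#' Averages a per-channel set of concentration time courses across the
#' first `n_cycles` answer cycles and across channels into one 60-s epoch:
#' 15 s pre-task rest, the 30-s task block, 15 s post-task rest.  The epoch
#' is re-zeroed to the mean of its pre-task segment, and the per-sample
#' dispersion (standard error across the averaged cycle x channel units) is
#' attached.
#'
#' @param series_by_channel list of numeric per-frame series (one per
#'   channel), all on the protocol's frame grid
#' @param protocol a `protocol_design`
#' @param n_cycles number of leading cycles to average (<= protocol cycles)
#' @param pre_s,post_s rest context on either side of the task block, s
#' @return an `epoch` object: `values`, `se`, `time_s` (relative to task
#'   onset), `task` (logical), `n_cycles_used`, `n_channels`
#' @export
average_epochs <- function(series_by_channel, protocol, n_cycles = protocol$n_cycles,
                           pre_s = 15, post_s = 15) {
  if (n_cycles < 1 || n_cycles > protocol$n_cycles)
    stop("n_cycles must be in [1, protocol cycles]")
  if (!is.list(series_by_channel)) series_by_channel <- list(series_by_channel)
  dt <- protocol$frame_period_s
  npre <- round(pre_s / dt)
  ntask <- round(protocol$answer_s / dt)
  npost <- round(post_s / dt)
  if (npre > protocol$frames_baseline)
    stop("epoch window extends before the start of the run")
  len <- npre + ntask + npost
  units <- list()
  for (ch in series_by_channel) {
    if (length(ch) != protocol$frames_per_run) stop("series length != frames per run")
    for (c_i in seq_len(n_cycles)) {
      on <- protocol$answer_onset_frames[c_i]
      units[[length(units) + 1]] <- ch[(on - npre):(on - npre + len - 1)]
    }
  }
  U <- do.call(cbind, units)
  vals <- rowMeans(U)
  se <- apply(U, 1, stats::sd) / sqrt(ncol(U))
  vals <- vals - mean(vals[seq_len(npre)])
  structure(list(values = vals, se = se,
                 time_s = (seq_len(len) - 0.5) * dt - pre_s,
                 task = seq_len(len) > npre & seq_len(len) <= npre + ntask,
                 n_cycles_used = n_cycles,
                 n_channels = length(series_by_channel),
                 sampling_period_s = dt, pre_s = pre_s,
                 task_s = protocol$answer_s),
            class = "epoch")
}

#' @export
print.epoch <- function(x, ...) {
  cat(sprintf("epoch: %d samples (%gs pre + %gs task + %gs post), %d cycles x %d channels\n",
              length(x$values), x$pre_s, x$task_s,
              length(x$values) * x$sampling_period_s - x$pre_s - x$task_s,
              x$n_cycles_used, x$n_channels))
  invisible(x)
}

#' Median signal shift (SM)
#'
#' Difference between the median signal during the task block, excluding
#' its first `exclude_s` seconds, and the median of the preceding rest
#' segment.
#'
#' @param epoch an `epoch`
#' @param exclude_s initial task seconds excluded from the task median
#' @return SM, in the epoch's units (uM for concentrations)
#' @export
feature_SM <- function(epoch, exclude_s = 10) {
  if (epoch$task_s <= exclude_s) stop("task segment must be longer than the exclusion")
  task <- epoch$task & epoch$time_s >= exclude_s
  pre <- epoch$time_s < 0
  stats::median(epoch$values[task]) - stats::median(epoch$values[pre])
}

#' Early task slope (SS)
#'
#' Ordinary least-squares slope of the first `slope_window_s` seconds of the
#' task block.
#'
#' @param epoch an `epoch`
#' @param slope_window_s slope window from task onset, s
#' @return slope in units per second
#' @export
feature_SS <- function(epoch, slope_window_s = 16) {
  if (slope_window_s > epoch$task_s) stop("slope window exceeds the task block")
  sel <- epoch$task & epoch$time_s < slope_window_s
  if (sum(sel) < 3) stop("fewer than 3 samples in the slope window")
  tt <- epoch$time_s[sel]
  yy <- epoch$values[sel]
  sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
}

#' Contrast-to-noise ratio (CNR)
#'
#' Mean task-rest signal difference divided by the standard deviation of
#' the preceding rest segment.
#'
#' @param epoch an `epoch`
#' @return CNR, dimensionless
#' @export
feature_CNR <- function(epoch) {
  pre <- epoch$time_s < 0
  s <- stats::sd(epoch$values[pre])
  if (!is.finite(s) || s == 0) stop("degenerate rest period: zero variance")
  (mean(epoch$values[epoch$task]) - mean(epoch$values[pre])) / s
}

#' Correlation with the theoretical activation model (r)
#'
#' Pearson correlation between the full epoch and the activation-model
#' epoch (boxcar over the task blocks convolved with the hemodynamic
#' kernel, epoch-extracted and re-zeroed identically).
#'
#' @param epoch an `epoch`
#' @param protocol the `protocol_design` the epoch was built from
#' @param peak_s hemodynamic kernel time-to-peak, s
#' @return Pearson correlation between -1 and 1
#' @export
feature_r <- function(epoch, protocol, peak_s = 7) {
  if (stats::sd(epoch$values) == 0) stop("zero-variance epoch")
  model <- model_epoch(protocol, epoch, peak_s)
  stats::cor(epoch$values, model$values)
}

# activation-model series pushed through the identical epoch extraction
model_epoch <- function(protocol, epoch, peak_s = 7) {
  shape <- activation_model(protocol, peak_s)
  average_epochs(list(shape), protocol, n_cycles = epoch$n_cycles_used,
                 pre_s = epoch$pre_s,
                 post_s = length(epoch$values) * epoch$sampling_period_s -
                   epoch$pre_s - epoch$task_s)
}

#' Extract the oxyhemoglobin feature vector from an epoch
#'
#' Applies [feature_SM()], [feature_SS()], [feature_CNR()] and
#' [feature_r()].  A degenerate (zero-variance) rest segment, which can only
#' arise on noiseless synthetic input, yields `CNR = 0` and `r = 0` with a
#' `degenerate` flag instead of an error so that noise-free fixtures can
#' flow through the pipeline.
#'
#' @param epoch an `epoch` (oxyhemoglobin)
#' @param protocol the `protocol_design`
#' @param peak_s hemodynamic kernel time-to-peak, s
#' @param slope_window_s see [feature_SS()]
#' @return named list `SM`, `SS`, `CNR`, `r`, `degenerate`
#' @export
extract_features <- function(epoch, protocol, peak_s = 7, slope_window_s = 16) {
  degen <- stats::sd(epoch$values[epoch$time_s < 0]) == 0 ||
    stats::sd(epoch$values) == 0
  list(SM = feature_SM(epoch),
       SS = feature_SS(epoch, slope_window_s),
       CNR = if (degen) 0 else feature_CNR(epoch),
       r = if (degen) 0 else feature_r(epoch, protocol, peak_s),
       degenerate = degen)
}
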