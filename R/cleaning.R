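#' Motion-artifact detection by moving standard deviation
#'
#' Flags samples whose centred moving standard deviation exceeds `k` times
#' the median moving standard deviation of the whole series.  Flagged runs
#' separated by less than one window are merged into a single artifact
#' segment.
#'
#' @param x numeric series
#' @param sampling_period_s sampling period, s
#' @param window_s moving-window length, s (must cover >= 2 samples)
#' @param k threshold multiplier on the median moving SD
#' @return logical artifact mask, same length as `x`
#' @export
detect_motion <- function(x, sampling_period_s = 0.3, window_s = 1.0, k = 3.0) {
  w <- max(2L, as.integer(round(window_s / sampling_period_s)))
  n <- length(x)
  if (n < w) stop("series shorter than the moving window")
  msd <- moving_sd(x, w)
  thr <- k * stats::median(msd, na.rm = TRUE)
  mask <- msd > thr
  mask[is.na(mask)] <- FALSE
  merge_gaps(mask, w)
}

# centred moving SD via cumulative sums of x and x^2 (edges: shrunken window)
moving_sd <- function(x, w) {
  n <- length(x)
  half <- w %/% 2
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + (w - half - 1L))
  m <- hi - lo
  s <- cs[hi + 1L] - cs[lo + 1L]
  s2 <- cs2[hi + 1L] - cs2[lo + 1L]
  v <- (s2 - s^2 / m) / pmax(1, m - 1)
  sqrt(pmax(0, v))
}

merge_gaps <- function(mask, w) {
  r <- rle(mask)
  if (length(r$lengths) > 2) {
    inner <- 2:(length(r$lengths) - 1)
    r$values[inner][!r$values[inner] & r$lengths[inner] < w] <- TRUE
  }
  inverse.rle(r)
}

#' Motion-artifact correction by spline subtraction
#'
#' Within each flagged segment a smoothing spline is fitted and subtracted,
#' and the segment is re-anchored so its level is continuous with the
#' neighbouring clean samples (movement-artifact-reduction style).
#' Unflagged samples are returned unchanged.
#'
#' @param x numeric series
#' @param mask logical artifact mask from [detect_motion()]
#' @param spar smoothing parameter of [stats::smooth.spline()] for the
#'   within-segment trend (high = smooth trend capturing the artifact)
#' @param anchor_n number of neighbouring clean samples used to re-anchor a
#'   corrected segment's level
#' @return a list of class `clean_series`: `values`, `artifact_mask`,
#'   `provenance`
#' @export
correct_motion <- function(x, mask, spar = 0.7, anchor_n = 10) {
  if (length(mask) != length(x)) stop("mask length mismatch")
  if (all(mask)) stop("artifact mask covers the entire series")
  y <- x
  if (any(mask)) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      idx <- starts[i]:ends[i]
      seg <- x[idx]
      trend <- if (length(idx) >= 8) {
        stats::smooth.spline(seq_along(seg), seg, spar = spar)$y
      } else if (length(idx) >= 3) {
        stats::fitted(stats::lm(seg ~ seq_along(seg)))
      } else rep(mean(seg), length(idx))
      resid <- seg - trend
      # anchor to the mean of the nearest clean neighbours
      left <- if (starts[i] > 1)
        x[setdiff(max(1, starts[i] - anchor_n):(starts[i] - 1), which(mask))]
      else numeric(0)
      right <- if (ends[i] < length(x))
        x[setdiff((ends[i] + 1):min(length(x), ends[i] + anchor_n), which(mask))]
      else numeric(0)
      anchor <- mean(c(left, right))
      if (!is.finite(anchor)) anchor <- mean(x[!mask])
      y[idx] <- resid + anchor
    }
  }
  structure(list(values = y, artifact_mask = mask,
                 provenance = list(step = "correct_motion", spar = spar)),
            class = "clean_series")
}

#' High-pass detrending by discrete-cosine-basis projection
#'
#' Removes all discrete-cosine regressors (including the constant) with
#' period longer than `cutoff_period_s` by exact least-squares projection,
#' the standard high-pass drift model for short block-design records.
#'
#' @param x numeric series
#' @param sampling_period_s sampling period, s
#' @param cutoff_period_s cut-off period, s; fluctuations slower than this
#'   are removed
#' @return `clean_series` with the residual (detrended) signal
#' @export
highpass_detrend <- function(x, sampling_period_s = 0.3, cutoff_period_s = 128) {
  n <- length(x)
  dur <- n * sampling_period_s
  if (dur <= cutoff_period_s / 2)
    stop("record shorter than half the cut-off period")
  # DCT-II regressor k has period 2*dur/k; drop k with period > cutoff
  kmax <- floor(2 * dur / cutoff_period_s)
  i <- seq_len(n) - 0.5
  X <- cbind(1, vapply(seq_len(kmax), function(k) cos(pi * k * i / n),
                       numeric(n)))
  res <- stats::lm.fit(X, x)$residuals
  structure(list(values = res,
                 provenance = list(step = "highpass_detrend",
                                   cutoff_period_s = cutoff_period_s,
                                   n_regressors = kmax + 1)),
            class = "clean_series")
}

#' Low-pass smoothing with a hemodynamic-width kernel
#'
#' Convolution with a unit-area Gaussian kernel of given full width at half
#' maximum (reflect-padded at the edges), suppressing fast components such
#' as the arterial pulsation while leaving hemodynamic-scale structure
#' intact.
#'
#' @param x numeric series
#' @param sampling_period_s sampling period, s
#' @param fwhm_s kernel full width at half maximum, s (>= 2 samples)
#' @return `clean_series` with the smoothed signal
#' @export
smooth_hrf <- function(x, sampling_period_s = 0.3, fwhm_s = 4.0) {
  if (fwhm_s < 2 * sampling_period_s) stop("fwhm must span at least 2 samples")
  sigma <- fwhm_s / (2 * sqrt(2 * log(2))) / sampling_period_s
  r <- max(1L, ceiling(4 * sigma))
  kern <- exp(-0.5 * ((-r):r / sigma)^2)
  kern <- kern / sum(kern)
  xp <- c(x[r:1], x, x[length(x):(length(x) - r + 1)])
  sm <- stats::filter(xp, kern, sides = 2)[(r + 1):(r + length(x))]
  structure(list(values = as.numeric(sm),
                 provenance = list(step = "smooth_hrf", fwhm_s = fwhm_s)),
            class = "clean_series")
}

#' Standard cleaning chain for a mean-time-of-flight change series
#'
#' Applies, in the fixed published order: motion detection and spline
#' correction, cosine-basis detrending, hemodynamic smoothing.
#'
#' @param x numeric series (typically `delta_t` of an `mtof_series`)
#' @param sampling_period_s sampling period, s
#' @param window_s,k motion-detection parameters, see [detect_motion()]
#' @param spar motion-correction spline parameter, see [correct_motion()]
#' @param cutoff_period_s detrending cut-off, see [highpass_detrend()]
#' @param fwhm_s smoothing kernel width, see [smooth_hrf()]
#' @return `clean_series` with accumulated provenance and the artifact mask
#' @export
clean_timecourse <- function(x, sampling_period_s = 0.3, window_s = 1.0,
                             k = 3.0, spar = 0.7, cutoff_period_s = 128,
                             fwhm_s = 4.0) {
  mask <- detect_motion(x, sampling_period_s, window_s, k)
  mc <- correct_motion(x, mask, spar)
  dt <- highpass_detrend(mc$values, sampling_period_s, cutoff_period_s)
  sm <- smooth_hrf(dt$values, sampling_period_s, fwhm_s)
  structure(list(values = sm$values, artifact_mask = mask,
                 provenance = list(mc$provenance, dt$provenance,
                                   sm$provenance)),
            class = "clean_series")
}
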