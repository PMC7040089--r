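#' Bin photon records into a DTOF frame
#'
#' Rebuilds the expected (noise-free) distribution of times-of-flight from a
#' photon record set under a given per-layer absorption, together with the
#' weight-averaged per-layer pathlength of each arrival-time bin.  The
#' per-bin mean pathlengths drive the fast first-order DTOF perturbation
#' used by the run simulator.
#'
#' @param records a `photon_records` object
#' @param bin_edges_ps increasing vector of bin edges, ps
#' @param mu_a per-layer absorption (mm^-1); defaults to the baseline
#'   absorption of the medium the records were generated in
#' @return a list of class `dtof_template`: `counts` (expected weight per
#'   bin), `bin_edges_ps`, `layer_path_means` (bins x layers, weighted mean
#'   pathlength of photons in each bin), `n_outside` (photons outside the
#'   bin range, also signalled as a warning)
#' @export
bin_photon_records <- function(records, bin_edges_ps,
                               mu_a = medium_mua(records$meta$medium)) {
  if (is.unsorted(bin_edges_ps, strictly = TRUE)) stop("bin edges must be increasing")
  L <- records$layer_pathlengths_mm
  K <- ncol(L)
  w <- records_weights(records, mu_a)
  t <- records$arrival_time_ps
  nb <- length(bin_edges_ps) - 1
  idx <- findInterval(t, bin_edges_ps, rightmost.closed = TRUE)
  inside <- idx >= 1 & idx <= nb
  n_outside <- sum(!inside)
  if (n_outside > 0)
    warning(sprintf("%d photons fall outside the bin range and were excluded",
                    n_outside))
  counts <- numeric(nb)
  lpm <- matrix(0, nb, K)
  if (any(inside)) {
    g <- idx[inside]
    agg_w <- rowsum(w[inside], g)
    rows <- as.integer(rownames(agg_w))
    counts[rows] <- agg_w[, 1]
    agg_l <- rowsum(L[inside, , drop = FALSE] * w[inside], g)
    nz <- counts[rows] > 0
    lpm[rows[nz], ] <- agg_l[nz, , drop = FALSE] / counts[rows][nz]
  } else {
    warning("empty record set in range: all-zero frame")
  }
  structure(list(counts = counts, bin_edges_ps = bin_edges_ps,
                 layer_path_means = lpm, n_outside = n_outside,
                 mu_a = mu_a),
            class = "dtof_template")
}

#' Mean-time-of-flight sensitivity factors from photon records
#'
#' Computes, for every layer, the derivative of the mean time-of-flight with
#' respect to that layer's absorption coefficient by exact per-photon
#' reweighting and a forward finite difference, and sums the brain-layer
#' values into the brain sensitivity factor (MTSF) used to convert
#' mean-time-of-flight changes into brain absorption changes.  All factors
#' are negative wherever photons actually traverse the layer: increasing
#' absorption preferentially removes late, long-path photons and shortens
#' the mean arrival time.
#'
#' Monte-Carlo standard errors are attached (delta-method linearisation of
#' the weighted-mean difference).
#'
#' @param records a `photon_records` object
#' @param medium the layered medium (defaults to the one the records were
#'   generated in; its `brain_layers` defines the brain sum)
#' @param delta_mua finite-difference step, mm^-1 (0 < delta <= 0.01)
#' @return a list of class `sensitivity_factors`: `per_layer_mtsf` (ps mm),
#'   `mtsf` (brain sum, ps mm), `per_layer_se`, `mtsf_se`, `brain_layers`,
#'   `delta_mua`, `meta`
#' @export
compute_mtsf <- function(records, medium = records$meta$medium,
                         delta_mua = 0.001) {
  if (!(delta_mua > 0 && delta_mua <= 0.01))
    stop("delta_mua must be in (0, 0.01] mm^-1")
  L <- records$layer_pathlengths_mm
  if (nrow(L) == 0) stop("empty record set")
  K <- ncol(L)
  t <- records$arrival_time_ps
  mu0 <- medium_mua(medium)
  w0 <- records_weights(records, mu0)
  wm0 <- mean(w0)
  m0 <- sum(w0 * t) / sum(w0)
  n <- length(t)

  per_layer <- numeric(K)
  per_se <- numeric(K)
  infl <- matrix(0, n, K) # per-photon influence of each finite difference
  for (k in seq_len(K)) {
    wk <- w0 * exp(-delta_mua * L[, k])
    mk <- sum(wk * t) / sum(wk)
    per_layer[k] <- (mk - m0) / delta_mua
    infl[, k] <- (wk * (t - mk) / mean(wk) - w0 * (t - m0) / wm0) / delta_mua
    per_se[k] <- stats::sd(infl[, k]) / sqrt(n)
  }
  brain <- medium$brain_layers
  if (all(L[, brain] == 0))
    stop("no detected photon traverses the brain layers; insufficient depth sampling")
  structure(list(per_layer_mtsf = per_layer,
                 mtsf = sum(per_layer[brain]),
                 per_layer_se = per_se,
                 mtsf_se = stats::sd(rowSums(infl[, brain, drop = FALSE])) / sqrt(n),
                 total_se = stats::sd(rowSums(infl)) / sqrt(n),
                 brain_layers = brain, delta_mua = delta_mua,
                 meta = records$meta[c("seed", "n_launched", "medium_hash")]),
            class = "sensitivity_factors")
}

#' @export
print.sensitivity_factors <- function(x, ...) {
  cat(sprintf("sensitivity_factors: brain MTSF = %.0f +/- %.0f ps mm (layers %s)\n",
              x$mtsf, x$mtsf_se, paste(range(x$brain_layers), collapse = "-")))
  invisible(x)
}

# Weighted covariance of arrival time with one layer's pathlength; in the
# small-perturbation limit MTSF_k = -Cov_w(t, l_k).  Returns the estimate
# and its delta-method standard error.
mtsf_covariance_oracle <- function(records, k,
                                   mu_a = medium_mua(records$meta$medium)) {
  t <- records$arrival_time_ps
  l <- records$layer_pathlengths_mm[, k]
  w <- records_weights(records, mu_a)
  mt <- sum(w * t) / sum(w)
  ml <- sum(w * l) / sum(w)
  cv <- sum(w * (t - mt) * (l - ml)) / sum(w)
  infl <- w * ((t - mt) * (l - ml) - cv) / mean(w)
  list(value = -cv, se = stats::sd(infl) / sqrt(length(t)))
}

#' Perturb a DTOF by per-layer absorption changes
#'
#' Forward model for an absorption perturbation.  Given photon records the
#' perturbation is exact (microscopic Beer-Lambert per photon); given only a
#' binned `dtof_template` the first-order approximation
#' `counts * exp(-sum_k delta_mua[k] * lbar[bin, k])` with per-bin mean
#' pathlengths is used and flagged in the result.
#'
#' @param baseline a `photon_records` or `dtof_template` object
#' @param delta_mua per-layer absorption change, mm^-1
#' @param bin_edges_ps required when `baseline` is a `photon_records`
#' @return a `dtof_template` with attribute `first_order` (TRUE for the
#'   binned approximation)
#' @export
perturb_dtof <- function(baseline, delta_mua, bin_edges_ps = NULL) {
  if (any(!is.finite(delta_mua))) stop("perturbation must be finite")
  if (inherits(baseline, "photon_records")) {
    if (is.null(bin_edges_ps)) stop("bin_edges_ps needed to bin photon records")
    out <- bin_photon_records(baseline, bin_edges_ps,
                              mu_a = medium_mua(baseline$meta$medium) + delta_mua)
    attr(out, "first_order") <- FALSE
    return(out)
  }
  if (!inherits(baseline, "dtof_template")) stop("unsupported baseline type")
  fac <- exp(-drop(baseline$layer_path_means %*% delta_mua))
  if (any(!is.finite(fac))) stop("perturbation produced non-finite weights")
  baseline$counts <- baseline$counts * fac
  baseline$mu_a <- baseline$mu_a + delta_mua
  attr(baseline, "first_order") <- TRUE
  baseline
}

#' Write / read sensitivity factors as JSON
#'
#' @param sens_by_wavelength named list mapping wavelength (nm, as character
#'   or numeric names) to `sensitivity_factors` objects
#' @param path file path
#' @return `path` (write) or a named list of per-wavelength entries (read)
#' @export
write_sensitivity_json <- function(sens_by_wavelength, path) {
  obj <- lapply(sens_by_wavelength, function(s)
    list(mtsf = s$mtsf, mtsf_se = s$mtsf_se,
         per_layer_mtsf = s$per_layer_mtsf, per_layer_se = s$per_layer_se,
         brain_layers = s$brain_layers, delta_mua = s$delta_mua,
         seed = s$meta$seed, n_launched = s$meta$n_launched,
         medium_hash = s$meta$medium_hash))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sensitivity_json
#' @export
read_sensitivity_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
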