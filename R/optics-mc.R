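#' Run layered Monte-Carlo photon transport
#'
#' Launches a pencil beam into a layered slab and records every photon that
#' escapes through the top surface inside the detection annulus.  Scattering
#' is isotropic at the reduced scattering rate (similarity relation) and
#' absorption is applied afterwards by weight attenuation
#' `exp(-sum_k mu_a[k] * l[k])`, so one photon set serves any absorption
#' values.  Photons are terminated once their total pathlength exceeds the
#' repetition window (`t_max_ps`).
#'
#' @param medium a [layered_medium()]
#' @param geom a [geometry()]
#' @param n_photons number of photon packets to launch
#' @param seed RNG seed (required: the record set is part of the analysis
#'   provenance and must be reproducible)
#' @param t_max_ps photons arriving later than this are discarded
#'   (default the 12.5-ns window of an 80-MHz pulse train)
#' @return a `photon_records` object with fields `arrival_time_ps`,
#'   `layer_pathlengths_mm` (matrix, photons x layers), `weight`
#'   (survival weight at the medium's baseline absorption) and `meta`
#' @export
run_photon_mc <- function(medium = layered_medium(), geom = geometry(),
                          n_photons = 1e6, seed, t_max_ps = 12500) {
  stopifnot(n_photons >= 1)
  if (missing(seed)) stop("an explicit seed is required")
  v <- light_speed(medium_n(medium))
  rho0 <- geom$source_detector_separation_mm
  hw <- geom$detector_halfwidth_mm
  set.seed(seed)
  res <- .mc_transport_cpp(medium_boundaries(medium), medium_mus(medium),
                           medium_n(medium), geom$external_refractive_index,
                           rho0 - hw, rho0 + hw,
                           as.integer(n_photons), v * t_max_ps)
  L <- res$layer_pathlengths
  if (nrow(L) == 0)
    stop("zero photons detected; launch more packets or widen the annulus")
  total <- rowSums(L)
  records <- structure(list(
    arrival_time_ps = total / v,
    layer_pathlengths_mm = L,
    weight = exp(-drop(L %*% medium_mua(medium))),
    exit_rho_mm = res$exit_rho,
    meta = list(n_launched = res$n_launched, n_exit_top = res$n_exit_top,
                seed = seed, t_max_ps = t_max_ps,
                medium = medium, geometry = geom,
                medium_hash = medium_hash(medium, geom))),
    class = "photon_records")
  records
}

#' @export
print.photon_records <- function(x, ...) {
  cat(sprintf(paste0("photon_records: %d detected / %g launched ",
                     "(%d layers, seed %s)\n"),
              length(x$arrival_time_ps), x$meta$n_launched,
              ncol(x$layer_pathlengths_mm), format(x$meta$seed)))
  cat(sprintf("  <t> = %.0f ps (unweighted), annulus hit fraction %.2e\n",
              mean(x$arrival_time_ps),
              length(x$arrival_time_ps) / x$meta$n_launched))
  invisible(x)
}

n_detected <- function(records) length(records$arrival_time_ps)

# Weights of the record set under an arbitrary per-layer absorption (mm^-1).
records_weights <- function(records, mu_a) {
  L <- records$layer_pathlengths_mm
  if (length(mu_a) != ncol(L)) stop("absorption length must match layer count")
  exp(-drop(L %*% mu_a))
}

#' Reweight photon records for a change in absorption
#'
#' Microscopic Beer-Lambert: each photon's weight is multiplied by
#' `exp(-sum_k delta_mu_a[k] * l[k])`.  This is the exact per-photon
#' forward model for an absorption perturbation.
#'
#' @param records a `photon_records` object
#' @param delta_mua per-layer absorption change (mm^-1), length = layers
#' @return a `photon_records` object with updated weights
#' @export
reweight_records <- function(records, delta_mua) {
  L <- records$layer_pathlengths_mm
  if (length(delta_mua) != ncol(L)) stop("delta_mua length must match layer count")
  f <- exp(-drop(L %*% delta_mua))
  if (any(!is.finite(f))) stop("perturbation produced non-finite weights")
  records$weight <- records$weight * f
  records
}

# Weighted moments of the arrival-time distribution with delta-method
# standard errors (linearisation of the ratio estimators).
weighted_time_moments <- function(t, w) {
  n <- length(t)
  wm <- mean(w)
  m1 <- sum(w * t) / sum(w)
  infl1 <- w * (t - m1) / wm
  v <- sum(w * (t - m1)^2) / sum(w)
  infl2 <- (w * ((t - m1)^2 - v)) / wm
  list(mean = m1, var = v,
       se_mean = stats::sd(infl1) / sqrt(n),
       se_var = stats::sd(infl2) / sqrt(n))
}
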