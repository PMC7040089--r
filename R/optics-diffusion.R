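# Internal-reflection boundary coefficient A for the extrapolated boundary
# (Groenhuis-style polynomial in the relative index n_in/n_out).
boundary_A <- function(n_rel) {
  if (abs(n_rel - 1) < 1e-12) return(1)
  rd <- -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  (1 + rd) / (1 - rd)
}

#' Time-resolved diffuse reflectance of a homogeneous semi-infinite medium
#'
#' Closed-form diffusion solution (isotropic point source at one transport
#' mean free path, extrapolated-boundary image dipole) for the time-resolved
#' reflectance at radial distance `rho_mm`.  Used to seed and cross-check the
#' Monte-Carlo model; the absolute scale is arbitrary.
#'
#' @param rho_mm source-detector separation, mm
#' @param time_ps strictly increasing vector of positive times, ps
#' @param props an [optical_layer()] giving mu_a, mu_s' and n
#' @param external_n refractive index above the surface
#' @return reflectance per unit area and time (arbitrary scale), same length
#'   as `time_ps`
#' @export
homogeneous_tr_reflectance <- function(rho_mm, time_ps, props,
                                       external_n = 1.0) {
  if (any(time_ps <= 0)) stop("times must be positive")
  if (is.unsorted(time_ps, strictly = TRUE)) stop("time grid must be strictly increasing")
  if (!(props$mu_s_prime > 0)) stop("diffusion solution requires mu_s_prime > 0")
  v <- light_speed(props$refractive_index)
  D <- 1 / (3 * props$mu_s_prime)
  z0 <- 1 / props$mu_s_prime
  zb <- 2 * D * boundary_A(props$refractive_index / external_n)
  s <- 4 * D * v * time_ps
  (4 * pi * D * v)^(-3 / 2) * time_ps^(-5 / 2) *
    exp(-props$mu_a * v * time_ps - rho_mm^2 / s) *
    0.5 * (z0 * exp(-z0^2 / s) + (z0 + 2 * zb) * exp(-(z0 + 2 * zb)^2 / s))
}

#' Diffusion-theory mean time-of-flight over a detection annulus
#'
#' Numerically integrates the homogeneous time-resolved reflectance over the
#' annular detection band and a finite time window and returns the first
#' moment.  Serves as the independent oracle for the Monte-Carlo
#' arrival-time distribution.
#'
#' @param geom a [geometry()]
#' @param props an [optical_layer()]
#' @param t_max_ps upper limit of the time window, ps
#' @param n_t,n_rho quadrature grid sizes
#' @return list with `mean_ps` and `var_ps2`
#' @export
diffusion_mtof <- function(geom = geometry(), props = optical_layer(Inf),
                           t_max_ps = 12500, n_t = 6000, n_rho = 41) {
  rho0 <- geom$source_detector_separation_mm
  hw <- geom$detector_halfwidth_mm
  rho <- seq(rho0 - hw, rho0 + hw, length.out = n_rho)
  tt <- seq(t_max_ps / n_t, t_max_ps, length.out = n_t)
  # weight each radius by its annular circumference (trapezoid in rho)
  wr <- rho * c(0.5, rep(1, n_rho - 2), 0.5)
  R <- vapply(rho, function(r)
    homogeneous_tr_reflectance(r, tt, props, geom$external_refractive_index),
    numeric(n_t))
  curve <- drop(R %*% wr)
  m <- sum(curve * tt) / sum(curve)
  v2 <- sum(curve * (tt - m)^2) / sum(curve)
  list(mean_ps = m, var_ps2 = v2)
}
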