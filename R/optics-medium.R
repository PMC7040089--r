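#' @useDynLib trfnirs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Speed of light in vacuum, mm/ps.  Photon speed in tissue is c/n.
C_MM_PER_PS <- 0.299792458

#' Speed of light in a medium
#'
#' @param refractive_index refractive index (dimensionless, >= 1)
#' @return speed in mm/ps
#' @export
light_speed <- function(refractive_index = 1.4) {
  stopifnot(refractive_index >= 1)
  C_MM_PER_PS / refractive_index
}

#' Optical properties of one tissue layer
#'
#' @param thickness_mm layer thickness in mm; `Inf` marks a semi-infinite
#'   terminal layer
#' @param mu_a absorption coefficient, mm^-1 (>= 0)
#' @param mu_s_prime reduced scattering coefficient, mm^-1 (> 0)
#' @param refractive_index refractive index (>= 1)
#' @return an `optical_layer` object
#' @export
optical_layer <- function(thickness_mm, mu_a = 0.017, mu_s_prime = 1.0,
                          refractive_index = 1.4) {
  if (!(thickness_mm > 0)) stop("layer thickness must be positive (Inf for semi-infinite)")
  if (mu_a < 0) stop("mu_a must be >= 0")
  if (!(mu_s_prime > 0)) stop("mu_s_prime must be > 0")
  if (refractive_index < 1) stop("refractive_index must be >= 1")
  structure(list(thickness_mm = thickness_mm, mu_a = mu_a,
                 mu_s_prime = mu_s_prime, refractive_index = refractive_index),
            class = "optical_layer")
}

#' Layered head model
#'
#' An ordered stack of plane-parallel layers, scalp side on top.  The
#' default is the 10-layer slab model used throughout the package: ten
#' 2-mm layers (the last one extended to semi-infinity) with generic
#' head-like baseline properties, and layers 5-10 designated as brain.
#'
#' @param layers list of [optical_layer()] objects, top first
#' @param brain_layers integer indices (1-based) of the layers treated as
#'   brain when summing sensitivity factors
#' @return a `layered_medium` object
#' @export
layered_medium <- function(layers = NULL, brain_layers = 5:10) {
  if (is.null(layers)) {
    layers <- lapply(1:10, function(k)
      optical_layer(thickness_mm = if (k == 10) Inf else 2,
                    mu_a = 0.017, mu_s_prime = 1.0, refractive_index = 1.4))
  }
  K <- length(layers)
  if (K < 1) stop("need at least one layer")
  ok <- vapply(layers, inherits, logical(1), "optical_layer")
  if (!all(ok)) stop("all layers must be optical_layer objects")
  th <- vapply(layers, `[[`, numeric(1), "thickness_mm")
  if (any(!is.finite(th[-K]))) stop("only the last layer may be semi-infinite")
  if (!all(brain_layers %in% seq_len(K))) stop("brain_layers out of range")
  n <- vapply(layers, `[[`, numeric(1), "refractive_index")
  if (length(unique(n)) != 1)
    stop("the photon-transport model requires a uniform refractive index")
  structure(list(layers = layers, brain_layers = as.integer(sort(brain_layers))),
            class = "layered_medium")
}

#' @export
print.layered_medium <- function(x, ...) {
  K <- length(x$layers)
  cat(sprintf("layered_medium: %d layers, brain = {%s}\n",
              K, paste(x$brain_layers, collapse = ",")))
  for (k in seq_len(K)) {
    l <- x$layers[[k]]
    cat(sprintf("  %2d: d=%5s mm  mu_a=%.4f  mu_s'=%.3f  n=%.2f\n",
                k, format(l$thickness_mm), l$mu_a, l$mu_s_prime,
                l$refractive_index))
  }
  invisible(x)
}

medium_mua <- function(medium) vapply(medium$layers, `[[`, numeric(1), "mu_a")
medium_mus <- function(medium) vapply(medium$layers, `[[`, numeric(1), "mu_s_prime")
medium_n <- function(medium) medium$layers[[1]]$refractive_index
medium_boundaries <- function(medium) {
  th <- vapply(medium$layers, `[[`, numeric(1), "thickness_mm")
  K <- length(th)
  if (K == 1) return(numeric(0))
  cumsum(th[-K])
}

# stable fingerprint of the optical model, recorded in caches/outputs
medium_hash <- function(medium, geometry = NULL) {
  s <- paste(c(medium_mua(medium), medium_mus(medium), medium_n(medium),
               vapply(medium$layers, `[[`, numeric(1), "thickness_mm"),
               medium$brain_layers,
               if (!is.null(geometry))
                 c(geometry$source_detector_separation_mm,
                   geometry$detector_halfwidth_mm,
                   geometry$external_refractive_index)),
             collapse = "|")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
}

#' Source-detector measurement geometry
#'
#' @param source_detector_separation_mm centre separation between the source
#'   fibre and the detection annulus, mm
#' @param detector_halfwidth_mm half-width of the annular detection band, mm
#' @param external_refractive_index index of the medium above the surface
#' @return a `geometry` object
#' @export
geometry <- function(source_detector_separation_mm = 30,
                     detector_halfwidth_mm = 2,
                     external_refractive_index = 1.0) {
  if (!(source_detector_separation_mm > 0)) stop("separation must be > 0")
  if (!(detector_halfwidth_mm > 0)) stop("detector half-width must be > 0")
  structure(list(source_detector_separation_mm = source_detector_separation_mm,
                 detector_halfwidth_mm = detector_halfwidth_mm,
                 external_refractive_index = external_refractive_index),
            class = "geometry")
}
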