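#' Molar extinction coefficient table
#'
#' Loads a two-wavelength extinction table and converts it to the natural-log
#' absorption convention used throughout the package:
#' `mu_a [mm^-1] = eps [mm^-1 uM^-1] * C [uM]`.  The shipped table carries
#' published compiled hemoglobin spectra in the conventional
#' M^-1 cm^-1 (log10) units; the conversion factor is `ln(10) * 1e-7`.
#'
#' @param path CSV with columns `wavelength_nm`, `eps_hbo2`, `eps_hb`
#'   (M^-1 cm^-1, log10); defaults to the table shipped with the package
#' @param wavelengths the two wavelengths to keep, nm
#' @return an `extinction_table`: 2 x 2 matrix `E` (rows = wavelengths,
#'   cols = HbO2, Hb) in mm^-1 uM^-1, plus `wavelengths` and `source`
#' @export
extinction_table <- function(path = system.file("extdata",
                               "extinction_hbo2_hb.csv", package = "trfnirs"),
                             wavelengths = c(760, 830)) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("wavelength_nm", "eps_hbo2", "eps_hb")
  if (!all(need %in% names(tab))) stop("extinction CSV missing required columns")
  rows <- match(wavelengths, tab$wavelength_nm)
  if (anyNA(rows)) stop("extinction table lacks the requested wavelengths")
  conv <- log(10) * 1e-7 # M^-1 cm^-1 -> mm^-1 uM^-1, natural log
  E <- conv * as.matrix(tab[rows, c("eps_hbo2", "eps_hb")])
  dimnames(E) <- list(as.character(wavelengths), c("HbO2", "Hb"))
  kap <- kappa(E, exact = TRUE)
  if (kap >= 100)
    stop(sprintf("extinction matrix ill-conditioned (condition number %.1f)", kap))
  structure(list(E = E, wavelengths = wavelengths,
                 source = tab$source[rows[1]]),
            class = "extinction_table")
}

#' Absorption changes from mean-time-of-flight changes
#'
#' The moment-based inversion: `delta_mua(lambda) = delta_t / MTSF(lambda)`,
#' where MTSF is the (negative) brain sensitivity factor of the mean
#' time-of-flight.  A decrease in the mean time-of-flight therefore maps to
#' an absorption increase.
#'
#' @param delta_t numeric vector of mean-time-of-flight changes, ps
#' @param mtsf brain sensitivity factor for this wavelength, ps mm (nonzero,
#'   expected negative); either a scalar or a `sensitivity_factors` object
#' @return per-frame absorption change, mm^-1
#' @export
delta_mua_from_mtof <- function(delta_t, mtsf) {
  if (inherits(mtsf, "sensitivity_factors")) mtsf <- mtsf$mtsf
  if (!is.finite(mtsf) || mtsf == 0) stop("MTSF must be finite and nonzero")
  delta_t / mtsf
}

#' Two-wavelength inversion to hemoglobin concentration changes
#'
#' Solves, frame by frame, the 2 x 2 linear system
#' `delta_mua(lambda) = eps_HbO2(lambda) dC_HbO2 + eps_Hb(lambda) dC_Hb`
#' for the oxy- and deoxyhemoglobin concentration changes.
#'
#' @param mua_by_wavelength named list (or 2-column matrix) of absorption
#'   change series, mm^-1, names matching the table's wavelengths
#' @param table an [extinction_table()]
#' @return an `hb_timecourse`: `delta_hbo2`, `delta_hb` in uM
#' @export
hb_concentrations <- function(mua_by_wavelength, table = extinction_table()) {
  wl <- as.character(table$wavelengths)
  if (is.list(mua_by_wavelength)) {
    if (!all(wl %in% names(mua_by_wavelength)))
      stop("absorption series missing for a configured wavelength")
    M <- cbind(mua_by_wavelength[[wl[1]]], mua_by_wavelength[[wl[2]]])
  } else M <- mua_by_wavelength
  if (ncol(M) != 2) stop("need exactly two wavelengths")
  sol <- t(solve(table$E, t(M)))
  structure(list(delta_hbo2 = sol[, 1], delta_hb = sol[, 2],
                 wavelengths = table$wavelengths),
            class = "hb_timecourse")
}

#' Forward Beer-Lambert: concentrations to absorption changes
#'
#' The exact forward counterpart of [hb_concentrations()]; used by the run
#' simulator to inject activation and by round-trip tests.
#'
#' @param delta_hbo2,delta_hb concentration change series, uM
#' @param table an [extinction_table()]
#' @return matrix (frames x 2) of absorption changes, mm^-1, columns named
#'   by wavelength
#' @export
mua_from_hb <- function(delta_hbo2, delta_hb, table = extinction_table()) {
  M <- cbind(HbO2 = delta_hbo2, Hb = delta_hb) %*% t(table$E)
  colnames(M) <- as.character(table$wavelengths)
  M
}
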