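#' Debye-Hueckel screening length of a monovalent electrolyte
#'
#' Evaluates the screening length
#' \deqn{\kappa^{-1} = \sqrt{\frac{\epsilon_r \epsilon_0 k_B T}{2 N_A e^2 I}}}
#' for a 1:1 electrolyte with CODATA physical constants, returning Angstrom.
#' The result halves when the ionic strength quadruples.
#'
#' The simulator's `kappa` parameter is an inverse screening length in
#' 1/Angstrom entering the exponential screening factors of the electrostatic
#' and head-tail polarization terms; because the solvent is implicit, the
#' mapping from a real ionic strength to the model's `kappa` is a documented
#' convenience, not a calibration claim.
#'
#' @param ionic_strength Ionic strength I, mol/L (> 0).
#' @param temperature Absolute temperature, K.
#' @param relative_permittivity Relative permittivity of the solvent
#'   (dimensionless; 78.5 for water near room temperature).
#' @return Screening length \eqn{\kappa^{-1}} in Angstrom.
#' @export
#' @examples
#' debye_length(0.15)  # physiological saline, ~7.9 Angstrom
debye_length <- function(ionic_strength, temperature = 300,
                         relative_permittivity = 78.5) {
  if (!is.numeric(ionic_strength) || any(ionic_strength <= 0)) {
    stop("ionic strength must be > 0", call. = FALSE)
  }
  if (temperature <= 0 || relative_permittivity <= 0) {
    stop("temperature and permittivity must be > 0", call. = FALSE)
  }
  eps0 <- 8.8541878128e-12   # F/m
  kB <- 1.380649e-23         # J/K
  NA_ <- 6.02214076e23       # 1/mol
  e <- 1.602176634e-19       # C
  I_m3 <- ionic_strength * 1000          # mol/m^3
  lam <- sqrt(relative_permittivity * eps0 * kB * temperature /
                (2 * NA_ * e^2 * I_m3)) # meters
  lam * 1e10
}

#' The calibration kappa grid
#'
#' The eleven screening-factor values 0.0, 0.1, ..., 1.0 (1/Angstrom) swept
#' during weight calibration, generated decimally (integer tenths) so that
#' the values are exact dictionary keys.
#'
#' @return Numeric vector of length 11.
#' @export
kappa_grid <- function() {
  (0:10) / 10
}
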