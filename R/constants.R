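# Centralized physical constants (CODATA 2018) and unit conversions.
# Package-wide unit conventions: energy in eV, vibrational frequencies and
# state-count grains in cm^-1, masses in amu, lengths in Angstrom, dipoles
# in Debye, cross sections in Angstrom^2, temperatures in K, time in s.
.const <- list(
  cm1_to_ev    = 1.239841984e-4,   # eV per cm^-1
  kb_ev        = 8.617333262e-5,   # Boltzmann constant, eV/K
  kb_j         = 1.380649e-23,     # Boltzmann constant, J/K
  h_ev_s       = 4.135667696e-15,  # Planck constant, eV s
  ev_j         = 1.602176634e-19,  # J per eV
  amu_kg       = 1.66053906660e-27,
  coulomb_ev_a = 14.399645,        # e^2/(4 pi eps0), eV Angstrom
  debye_e_a    = 0.2081943,        # e Angstrom per Debye
  mtorr_pa     = 0.1333223684,     # Pa per mTorr
  fwhm_to_sd   = 1 / 2.354820045   # Gaussian FWHM -> standard deviation
)

#' Physical constants used by gibkin
#'
#' Returns the named list of physical constants and unit-conversion factors
#' used throughout the package (CODATA 2018 values). All internal energetics
#' are carried in eV; see the individual names for the conversions.
#'
#' @return Named list of constants: `cm1_to_ev`, `kb_ev`, `kb_j`, `h_ev_s`,
#'   `ev_j`, `amu_kg`, `coulomb_ev_a` (\eqn{e^2/4\pi\epsilon_0} in eV
#'   Angstrom), `debye_e_a`, `mtorr_pa`, `fwhm_to_sd`.
#' @export
#' @examples
#' kin_constants()$kb_ev
kin_constants <- function() .const
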