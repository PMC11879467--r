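#' Scaled harmonic zero-point energy
#'
#' ZPE of a set of harmonic modes, \eqn{scale \times \sum h\nu_i/2},
#' returned in eV. The default scale factor 0.975 is the standard harmonic
#' correction applied to the frequency sets this package targets; set
#' `scale = 1` for unscaled ZPE.
#'
#' @param frequencies Vibrational frequencies in cm^-1, all > 0.
#' @param scale Dimensionless scale factor in (0, 1.2].
#' @return ZPE in eV (0 for an empty frequency set).
#' @export
#' @examples
#' zpe(1000, scale = 1)   # h*nu/2 for a single mode
zpe <- function(frequencies, scale = 0.975) {
  check_number(scale, "scale", 0, strict = TRUE)
  if (scale > 1.2) stop("`scale` must be in (0, 1.2]", call. = FALSE)
  if (length(frequencies) == 0L) return(0)
  if (any(frequencies <= 0))
    stop("all `frequencies` must be > 0", call. = FALSE)
  scale * sum(frequencies) * .const$cm1_to_ev / 2
}

#' Rigid-rotor/harmonic-oscillator thermal correction
#'
#' Thermal correction to the enthalpy at temperature `T` within the
#' RRHO approximation: harmonic vibrational thermal energy
#' \eqn{\sum h\nu_i/(e^{h\nu_i/k_BT}-1)}, classical rotation (3/2 kT for a
#' nonlinear rotor, kT linear, 0 for an atom), translation (3/2 kT), and
#' the kT enthalpy (PV) term. A transition state's imaginary mode is
#' stored separately on the species and therefore never enters the sum.
#'
#' @param sp A [species()].
#' @param T Temperature in K (> 0). Default 298.15 K, the convention for
#'   reported reaction enthalpies; ion internal temperatures in the beam
#'   are a separate setting (see [beam_conditions()]).
#' @return Thermal correction in eV.
#' @export
rrho_thermal_correction <- function(sp, T = 298.15) {
  check_number(T, "T", 0, strict = TRUE)
  kt <- .const$kb_ev * T
  vib <- 0
  if (length(sp$frequencies)) {
    hv <- sp$frequencies * .const$cm1_to_ev
    vib <- sum(hv / expm1(hv / kt))
  }
  rot <- switch(rotor_type(sp), atom = 0, linear = kt, nonlinear = 1.5 * kt)
  vib + rot + 1.5 * kt + kt
}

#' Broken-symmetry/high-spin energy pair
#'
#' Container for the two unrestricted solutions entering approximate spin
#' projection of a singlet diradical: the broken-symmetry (BS) singlet and
#' the high-spin (HS) triplet, each with its \eqn{\langle S^2 \rangle}
#' expectation value.
#'
#' @param E_BS,E_HS Electronic energies of the BS and HS states, eV.
#' @param S2_BS,S2_HS \eqn{\langle S^2 \rangle} of each state; requires
#'   `S2_HS > S2_BS >= 0`.
#' @return An object of class `spin_pair`.
#' @seealso [spin_project()]
#' @export
spin_pair <- function(E_BS, E_HS, S2_BS, S2_HS) {
  check_number(S2_BS, "S2_BS", 0)
  check_number(S2_HS, "S2_HS", 0)
  if (S2_HS <= S2_BS)
    stop("requires S2_HS > S2_BS", call. = FALSE)
  structure(list(E_BS = E_BS, E_HS = E_HS, S2_BS = S2_BS, S2_HS = S2_HS),
            class = "spin_pair")
}

#' Approximate spin projection of a diradical energy
#'
#' Removes spin contamination from a broken-symmetry singlet energy using
#' the high-spin state:
#' \deqn{E = \frac{\langle S^2\rangle^{HS}}{\langle S^2\rangle^{HS}-\langle S^2\rangle^{BS}} E^{BS}
#'        - \frac{\langle S^2\rangle^{BS}}{\langle S^2\rangle^{HS}-\langle S^2\rangle^{BS}} E^{HS}.}
#' Geometrically, this is the line through \eqn{(\langle S^2\rangle^{BS}, E^{BS})}
#' and \eqn{(\langle S^2\rangle^{HS}, E^{HS})} evaluated at \eqn{\langle S^2\rangle = 0}.
#'
#' @param pair A [spin_pair()].
#' @return Spin-projected energy in eV.
#' @export
#' @examples
#' spin_project(spin_pair(E_BS = -1.0, E_HS = -0.9, S2_BS = 1, S2_HS = 2))
spin_project <- function(pair) {
  stopifnot(inherits(pair, "spin_pair"))
  d <- pair$S2_HS - pair$S2_BS
  if (d == 0) stop("S2_HS equals S2_BS: spin projection undefined",
                   call. = FALSE)
  (pair$S2_HS / d) * pair$E_BS - (pair$S2_BS / d) * pair$E_HS
}

#' Charge-transfer endothermicity from adiabatic ionization potentials
#'
#' \eqn{\Delta H(0\,K)} for electron transfer from the neutral to the
#' parent cation: AIP(neutral) - AIP(parent). Negative values mean the
#' charge transfer is exothermic.
#'
#' @param aip_neutral AIP of the neutral reagent, eV (> 0).
#' @param aip_parent AIP of the species whose cation carries the charge,
#'   eV (> 0).
#' @return Endothermicity in eV.
#' @export
#' @examples
#' ct_endothermicity(9.04, 7.63)   # methylamine vs 9-methylguanine
ct_endothermicity <- function(aip_neutral, aip_parent) {
  check_number(aip_neutral, "aip_neutral", 0, strict = TRUE)
  check_number(aip_parent, "aip_parent", 0, strict = TRUE)
  aip_neutral - aip_parent
}

#' Proton-transfer threshold from gas-phase acidity and basicity
#'
#' \eqn{\Delta H} for moving a proton from the acid to the base:
#' acidity(donor site) - basicity(acceptor).
#'
#' @param acidity Gas-phase acidity of the deprotonation site, eV (> 0).
#' @param basicity Gas-phase basicity of the proton acceptor, eV (> 0).
#' @return Threshold in eV.
#' @export
#' @examples
#' pt_threshold(9.9, 9.32)
pt_threshold <- function(acidity, basicity) {
  check_number(acidity, "acidity", 0, strict = TRUE)
  check_number(basicity, "basicity", 0, strict = TRUE)
  acidity - basicity
}

#' Reaction enthalpy from per-species energetics
#'
#' Products-minus-reactants sum of electronic energy + scaled ZPE +
#' RRHO thermal correction at `T`. All species must carry electronic
#' energies on a common reference.
#'
#' @param reactants,products Lists of [species()] objects.
#' @param T Temperature in K, default 298.15.
#' @param zpe_scale ZPE scale factor passed to [zpe()].
#' @return Reaction enthalpy in eV.
#' @export
reaction_enthalpy <- function(reactants, products, T = 298.15,
                              zpe_scale = 0.975) {
  all_sp <- c(reactants, products)
  if (!all(vapply(all_sp, inherits, logical(1), "species")))
    stop("`reactants` and `products` must be lists of species objects",
         call. = FALSE)
  if (any(vapply(all_sp, function(s) is.null(s$electronic_energy),
                 logical(1))))
    stop("every species needs an `electronic_energy`", call. = FALSE)
  refs <- unique(vapply(all_sp, function(s) s$energy_ref, character(1)))
  if (length(refs) != 1L)
    stop("mixed electronic-energy references: ",
         paste(refs, collapse = ", "), call. = FALSE)
  h298 <- function(s) s$electronic_energy +
    zpe(s$frequencies, scale = zpe_scale) + rrho_thermal_correction(s, T)
  sum(vapply(products, h298, numeric(1))) -
    sum(vapply(reactants, h298, numeric(1)))
}
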