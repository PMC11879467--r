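# Synthetic-data generators: toy species, isotopologues, line-of-centers
# shaped cross-section curves, and the table of study constants used as
# fixed inputs throughout the package.

#' Generate a reproducible toy species
#'
#' Pseudo-random molecular species with plausible spectroscopic constants:
#' frequencies drawn uniformly in `freq_range` (sorted ascending),
#' rotational constants scaled inversely with mass, polarizability scaled
#' with mass, and a random dipole. Intended as a stand-in wherever a full
#' frequency set is needed but a real one is not available.
#'
#' @param seed RNG seed (mandatory: generators are bit-reproducible).
#' @param n_modes Number of vibrational modes (>= 0; 0 gives an atom-like
#'   species).
#' @param freq_range Length-2 positive interval for frequencies, cm^-1.
#'   Default 50-3500 cm^-1, the span of typical organic molecules.
#' @param mass Mass in amu (> 0).
#' @param charge Charge in elementary units.
#' @param name Species label.
#' @return A [species()].
#' @export
#' @examples
#' gen_species(seed = 1, n_modes = 15, mass = 34)
gen_species <- function(seed, n_modes, freq_range = c(50, 3500), mass,
                        charge = 0L, name = sprintf("toy-%d", seed)) {
  if (n_modes < 0) stop("`n_modes` must be >= 0", call. = FALSE)
  if (length(freq_range) != 2L || any(freq_range <= 0) ||
      freq_range[2] < freq_range[1])
    stop("`freq_range` must be a positive increasing interval",
         call. = FALSE)
  check_number(mass, "mass", 0, strict = TRUE)
  with_seed(seed, {
    freqs <- if (n_modes > 0)
      sort(stats::runif(n_modes, freq_range[1], freq_range[2])) else
        numeric()
    rot <- if (n_modes > 0) {
      base <- 60 / mass
      sort(base * stats::runif(3, 0.5, 1.5), decreasing = TRUE)
    } else numeric()
    alpha <- 0.08 * mass * stats::runif(1, 0.8, 1.2)
    dip <- stats::runif(1, 0, 4)
    species(name, mass = mass, charge = charge, frequencies = freqs,
            rotational_constants = rot, polarizability = alpha,
            dipole = dip)
  })
}

#' Derive an isotopologue by scaling selected frequencies
#'
#' Multiplies the selected modes by `ratio` (default \eqn{1/\sqrt{2}}, the
#' harmonic limit for H-to-D stretches) and increments the mass. The
#' isotopologue's ZPE is never larger than the parent's.
#'
#' @param sp Parent [species()].
#' @param scale_indices Integer indices of the modes to scale.
#' @param ratio Frequency scale factor in (0, 1].
#' @param mass_increment Mass change in amu (e.g. +3 for CH3 to CD3).
#' @return A [species()] with scaled frequencies.
#' @export
gen_isotopologue <- function(sp, scale_indices, ratio = 1 / sqrt(2),
                             mass_increment = 0) {
  stopifnot(inherits(sp, "species"))
  if (ratio <= 0 || ratio > 1)
    stop("`ratio` must be in (0, 1]", call. = FALSE)
  if (length(scale_indices) &&
      (any(scale_indices < 1) || any(scale_indices > length(sp$frequencies))))
    stop("`scale_indices` out of range", call. = FALSE)
  freqs <- sp$frequencies
  freqs[scale_indices] <- freqs[scale_indices] * ratio
  out <- sp
  out$frequencies <- freqs
  out$mass <- sp$mass + mass_increment
  out$name <- paste0(sp$name, "-iso")
  out
}

#' Generate a synthetic broadened cross-section curve with noise
#'
#' Runs the Monte Carlo convolution of the threshold law under the given
#' beam conditions and applies multiplicative Gaussian noise with
#' coefficient of variation `noise_cv`. The reported uncertainty column is
#' `noise_cv` times the model value, floored at 5% of the curve maximum so
#' below-threshold points keep a finite detection-noise level.
#'
#' @param params A [loc_params()].
#' @param conditions A [beam_conditions()].
#' @param e_grid Nominal center-of-mass energies, eV.
#' @param noise_cv Coefficient of variation of the noise (>= 0).
#' @param n_samples Monte Carlo draws per grid point.
#' @param seed RNG seed; the curve is bit-reproducible for a fixed seed.
#' @return A [cross_section_curve()].
#' @export
gen_curve <- function(params, conditions, e_grid, noise_cv = 0.05,
                      n_samples = 500, seed) {
  check_number(noise_cv, "noise_cv", 0)
  with_seed(seed, {
    base <- simulate_convolved_sigma(params, conditions, e_grid,
                                     n_samples = n_samples, seed = NULL)
    model <- base$sigma_a2
    err <- noise_cv * pmax(model, 0.05 * max(model))
    y <- pmax(model * (1 + noise_cv * stats::rnorm(length(model))), 0)
    cross_section_curve(e_grid, y, err)
  })
}

#' Fixed constants of the modeled beam study
#'
#' The scalar constants used as fixed inputs across the package and its
#' examples: reactant masses, adiabatic ionization potentials, gas-phase
#' acidities and basicity for the thermochemical cycles, transition-state
#' imaginary frequencies for tunneling factors, and the beam operating
#' parameters. Every entry carries its unit and a provenance string
#' describing where that kind of value comes from.
#'
#' @param name Optional constant name; when given, the bare value is
#'   returned.
#' @return With `name`: a single numeric value. Otherwise a data frame
#'   with columns `name`, `value`, `unit`, `provenance`.
#' @export
#' @examples
#' study_constants("aip_9mg")
#' head(study_constants())
study_constants <- function(name = NULL) {
  tab <- .study_constants
  if (is.null(name)) return(tab)
  hit <- match(name, tab$name)
  if (anyNA(hit))
    stop("unknown constant(s): ",
         paste(name[is.na(hit)], collapse = ", "), call. = FALSE)
  tab$value[hit]
}

.study_constants <- local({
  row <- function(name, value, unit, provenance)
    data.frame(name = name, value = value, unit = unit,
               provenance = provenance)
  rbind(
    row("mass_9mg_radical_cation", 165, "m/z",
        "mass-selected 9-methylguanine radical cation"),
    row("mass_9mg_deprotonated_cation", 164, "m/z",
        "mass-selected doubly oxidized (deprotonated) 9-methylguanine cation"),
    row("mass_cd3nh2", 34, "m/z",
        "d3-methylamine neutral target"),
    row("mass_ch3nh2", 31, "m/z",
        "methylamine neutral"),
    row("aip_9mg", 7.63, "eV",
        "literature adiabatic ionization potential of 9-methylguanine"),
    row("aip_ch3nh2", 9.04, "eV",
        "literature adiabatic ionization potential of methylamine"),
    row("acidity_9mg_cation_n1h", 10.0, "eV",
        "computed gas-phase acidity of the 9MG radical cation at N1-H"),
    row("acidity_9mg_cation_n2ha", 9.9, "eV",
        "computed gas-phase acidity of the 9MG radical cation at N2-Ha"),
    row("acidity_9mg_cation_n2hb", 10.1, "eV",
        "computed gas-phase acidity of the 9MG radical cation at N2-Hb"),
    row("basicity_ch3nh2", 9.32, "eV",
        "NIST-listed gas-phase basicity of methylamine"),
    row("imag_freq_methyl_ha_ch3", 169, "cm^-1",
        "imaginary frequency, methyl-H abstraction TS with CH3NH2"),
    row("imag_freq_methyl_ha_cd3", 140, "cm^-1",
        "imaginary frequency, methyl-H abstraction TS with CD3NH2"),
    row("imag_freq_amine_ha", 857, "cm^-1",
        "imaginary frequency, amine-H abstraction TS at N7"),
    row("imag_freq_amine_ha_deprot", 446, "cm^-1",
        "imaginary frequency, amine-H abstraction TS of the deprotonated cation"),
    row("fwhm_lab", 0.65, "eV",
        "upper bound on the lab-frame beam energy FWHM (retarding potential)"),
    row("ecm_spread", 0.1, "eV",
        "nominal center-of-mass energy spread implied by the lab FWHM"),
    row("pressure_min", 0.01, "mTorr",
        "scattering-cell pressure range, low end (single-collision regime)"),
    row("pressure_max", 0.015, "mTorr",
        "scattering-cell pressure range, high end"),
    row("path_length", 11, "cm",
        "effective scattering-cell length around the octopole"),
    row("zpe_scale", 0.975, "",
        "harmonic zero-point energy scale factor"),
    row("t_ion", 310, "K",
        "ion internal temperature after collisional thermalization"),
    row("detection_window", 1e-4, "s",
        "ion time of flight available before mass analysis (~1e2 us)"),
    row("loc_n_best_min", 2.4, "",
        "best-fit line-of-centers exponent, low end"),
    row("loc_n_best_max", 2.5, "",
        "best-fit line-of-centers exponent, high end"),
    row("e0_ct", 1.5, "eV",
        "fitted 0 K threshold for charge transfer"),
    row("e0_ct_unc", 0.2, "eV",
        "uncertainty of the charge-transfer threshold"),
    row("e0_pt", 0.6, "eV",
        "fitted 0 K threshold for proton transfer (radical cation)"),
    row("e0_pt_unc", 0.1, "eV",
        "uncertainty of the proton-transfer threshold"),
    row("e0_pt_deprot", 1.3, "eV",
        "fitted 0 K threshold for proton transfer (deprotonated cation)"),
    row("e0_pt_deprot_unc", 0.1, "eV",
        "uncertainty of the deprotonated-cation proton-transfer threshold"),
    row("efficiency_max_9mg", 0.07, "",
        "maximum reaction efficiency of the radical cation"),
    row("efficiency_max_deprot", 0.19, "",
        "maximum reaction efficiency of the deprotonated cation"),
    row("sigma_total_max", 17, "A (printed unit; presumably A^2)",
        "maximum total product cross section at the lowest energy"),
    row("rrkm_k_low", 8e8, "1/s",
        "crosslinking RRKM rate constant at the lowest collision energy"),
    row("rrkm_k_high", 3e9, "1/s",
        "crosslinking RRKM rate constant at 0.3 eV"),
    row("kie_low", 4, "",
        "methyl-H abstraction kH/kD, low end of the energy range"),
    row("kie_high", 5, "",
        "methyl-H abstraction kH/kD, high end of the energy range"),
    row("wigner_methyl_ha_ch3", 1.03, "",
        "Wigner tunneling factor, methyl-H abstraction with CH3NH2"),
    row("wigner_methyl_ha_cd3", 1.02, "",
        "Wigner tunneling factor, methyl-H abstraction with CD3NH2"),
    row("wigner_amine_ha", 1.7, "",
        "Wigner tunneling factor, amine-H abstraction at N7")
  )
})
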