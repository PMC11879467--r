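#' Line-of-centers threshold law parameters
#'
#' Parameter triple of the modified line-of-centers (LOC) model
#' \eqn{\sigma(E) = \sigma_0 (E + E_{vib} + E_{rot} - E_0)^n / E}:
#' normalization, 0 K threshold energy, and the exponent controlling how
#' efficiently translational energy drives the reaction.
#'
#' @param sigma0 Normalization, Angstrom^2 eV^(1-n) (>= 0).
#' @param e0 Threshold energy at 0 K, eV (>= 0).
#' @param n Exponent (> 0).
#' @return An object of class `loc_params`.
#' @export
loc_params <- function(sigma0, e0, n) {
  check_number(sigma0, "sigma0", 0)
  check_number(e0, "e0", 0)
  check_number(n, "n", 0, strict = TRUE)
  structure(list(sigma0 = sigma0, e0 = e0, n = n), class = "loc_params")
}

#' @export
print.loc_params <- function(x, ...) {
  cat(sprintf("<loc_params> sigma0 = %.4g A^2 eV^(1-n), E0 = %.4g eV, n = %.3g\n",
              x$sigma0, x$e0, x$n))
  invisible(x)
}

#' Beam and target conditions for the Monte Carlo convolution
#'
#' Everything the convolution of the threshold law samples from: the
#' lab-frame energy spread of the ion beam, the thermal motion of the
#' target gas (Doppler broadening), Boltzmann internal energies of both
#' partners, and the detection window used for kinetic-shift weighting.
#'
#' @param m_ion,m_neutral Masses in amu (> 0).
#' @param t_ion Internal (vibrational/rotational) temperature of the ion,
#'   K. Default 310 K, the collisional-thermalization temperature of the
#'   ion source.
#' @param t_neutral Temperature of the target gas, K (internal energies
#'   and translational Doppler motion). Default 310 K.
#' @param fwhm_lab Full width at half maximum of the lab-frame ion energy,
#'   eV (>= 0). Default 0.65 eV, the retarding-potential upper bound for
#'   the beam this package models.
#' @param detection_window Time available for a nascent product to form
#'   before mass analysis, s. Default 1e-4 s (the ~1e2 microsecond ion
#'   time of flight).
#' @param ion_frequencies,neutral_frequencies Vibrational frequencies of
#'   each partner, cm^-1 (may be empty).
#' @param ion_rotor,neutral_rotor `"nonlinear"`, `"linear"` or `"atom"`.
#' @return An object of class `beam_conditions`.
#' @export
beam_conditions <- function(m_ion, m_neutral, t_ion = 310, t_neutral = 310,
                            fwhm_lab = 0.65, detection_window = 1e-4,
                            ion_frequencies = numeric(),
                            neutral_frequencies = numeric(),
                            ion_rotor = "nonlinear",
                            neutral_rotor = "nonlinear") {
  check_number(m_ion, "m_ion", 0, strict = TRUE)
  check_number(m_neutral, "m_neutral", 0, strict = TRUE)
  check_number(t_ion, "t_ion", 0, strict = TRUE)
  check_number(t_neutral, "t_neutral", 0, strict = TRUE)
  check_number(fwhm_lab, "fwhm_lab", 0)
  check_number(detection_window, "detection_window", 0, strict = TRUE)
  if (length(ion_frequencies) && any(ion_frequencies <= 0))
    stop("`ion_frequencies` must be > 0", call. = FALSE)
  if (length(neutral_frequencies) && any(neutral_frequencies <= 0))
    stop("`neutral_frequencies` must be > 0", call. = FALSE)
  rotors <- c("nonlinear", "linear", "atom")
  structure(list(
    m_ion = m_ion, m_neutral = m_neutral, t_ion = t_ion,
    t_neutral = t_neutral, fwhm_lab = fwhm_lab,
    detection_window = detection_window,
    ion_frequencies = as.numeric(ion_frequencies),
    neutral_frequencies = as.numeric(neutral_frequencies),
    ion_rotor = match.arg(ion_rotor, rotors),
    neutral_rotor = match.arg(neutral_rotor, rotors)
  ), class = "beam_conditions")
}

#' Energy-resolved cross-section curve
#'
#' Container for \eqn{(E_{CM}, \sigma, \sigma_{err})} samples, the
#' experimental observable being fitted or simulated. Stored as a data
#' frame with columns `e_cm_ev`, `sigma_a2`, `sigma_err_a2`.
#'
#' @param e_cm Strictly increasing grid of center-of-mass energies, eV.
#' @param sigma Cross sections, Angstrom^2 (>= 0).
#' @param sigma_err Optional 1-sigma uncertainties, Angstrom^2.
#' @return A data frame of class `cross_section_curve`.
#' @export
cross_section_curve <- function(e_cm, sigma, sigma_err = NULL) {
  if (length(e_cm) != length(sigma))
    stop("`e_cm` and `sigma` must have equal length", call. = FALSE)
  if (any(diff(e_cm) <= 0))
    stop("`e_cm` must be strictly increasing", call. = FALSE)
  if (any(sigma < 0)) stop("`sigma` must be >= 0", call. = FALSE)
  if (is.null(sigma_err)) sigma_err <- rep(NA_real_, length(e_cm))
  if (length(sigma_err) != length(e_cm))
    stop("`sigma_err` must match the grid length", call. = FALSE)
  structure(data.frame(e_cm_ev = e_cm, sigma_a2 = sigma,
                       sigma_err_a2 = sigma_err),
            class = c("cross_section_curve", "data.frame"))
}

#' Read/write cross-section curves as delimited tables
#'
#' Tab-separated tables with header columns `E_CM_eV`, `sigma_A2` and
#' optional `sigma_err_A2`.
#'
#' @param path File path.
#' @return `read_curve`: a [cross_section_curve()]. `write_curve`: `path`,
#'   invisibly.
#' @export
read_curve <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  need <- c("E_CM_eV", "sigma_A2")
  if (!all(need %in% names(tab)))
    stop("curve table needs columns E_CM_eV and sigma_A2", call. = FALSE)
  err <- if ("sigma_err_A2" %in% names(tab)) tab$sigma_err_A2 else NULL
  cross_section_curve(tab$E_CM_eV, tab$sigma_A2, err)
}

#' @rdname read_curve
#' @param curve A [cross_section_curve()].
#' @export
write_curve <- function(curve, path) {
  out <- data.frame(E_CM_eV = curve$e_cm_ev, sigma_A2 = curve$sigma_a2,
                    sigma_err_A2 = curve$sigma_err_a2)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Modified line-of-centers cross section
#'
#' \eqn{\sigma(E) = \sigma_0 (E + E_{vib} + E_{rot} - E_0)^n / E} when the
#' energy excess is positive, else 0. Reactant internal energy counts
#' fully toward surmounting the threshold.
#'
#' @param e_cm Collision energy, eV (> 0; vectorized).
#' @param params A [loc_params()].
#' @param e_vib,e_rot Reactant vibrational/rotational energies, eV
#'   (recycled against `e_cm`).
#' @return Cross section in Angstrom^2.
#' @export
#' @examples
#' loc_sigma(1.0, loc_params(1, 0.5, 2), e_vib = 0.1, e_rot = 0.05)
loc_sigma <- function(e_cm, params, e_vib = 0, e_rot = 0) {
  stopifnot(inherits(params, "loc_params"))
  if (any(e_cm <= 0)) stop("`e_cm` must be > 0", call. = FALSE)
  excess <- e_cm + e_vib + e_rot - params$e0
  ifelse(excess > 0, params$sigma0 * excess^params$n / e_cm, 0)
}

# Sample total vibrational energy (eV, above ZPE) of a harmonic mode set
# from the per-mode quantum Boltzmann distribution.
sample_vib_energy <- function(frequencies, T, n) {
  e <- numeric(n)
  kt <- .const$kb_ev * T
  for (f in frequencies) {
    ratio <- f * .const$cm1_to_ev / kt
    p <- -expm1(-ratio)                 # 1 - exp(-hv/kT)
    e <- e + stats::rgeom(n, p) * f * .const$cm1_to_ev
  }
  e
}

# Sample classical rotational energy (eV): exponential for a linear rotor
# (2 dof), gamma(3/2) for a nonlinear rotor (3 dof), 0 for an atom.
sample_rot_energy <- function(rotor, T, n) {
  kt <- .const$kb_ev * T
  switch(rotor,
         atom = numeric(n),
         linear = stats::rexp(n) * kt,
         nonlinear = stats::rgamma(n, shape = 1.5) * kt)
}

#' Sample reactant internal energies from Boltzmann distributions
#'
#' Vibrational energy is drawn per mode from the quantum Boltzmann
#' distribution over harmonic levels (energies above ZPE); rotational
#' energy from the classical distribution for the stated rotor type.
#'
#' @param frequencies Vibrational frequencies, cm^-1.
#' @param rotor `"nonlinear"`, `"linear"` or `"atom"`.
#' @param T Temperature, K (> 0).
#' @param n_samples Number of draws.
#' @param seed Optional seed for reproducibility.
#' @return Data frame with columns `e_vib`, `e_rot` (eV).
#' @export
sample_internal_energy <- function(frequencies, rotor = "nonlinear", T,
                                   n_samples, seed = NULL) {
  check_number(T, "T", 0, strict = TRUE)
  rotor <- match.arg(rotor, c("nonlinear", "linear", "atom"))
  with_seed(seed, data.frame(
    e_vib = sample_vib_energy(frequencies, T, n_samples),
    e_rot = sample_rot_energy(rotor, T, n_samples)
  ))
}

#' Monte Carlo convolution of the threshold law over beam broadening
#'
#' For each nominal center-of-mass energy: draws the lab-frame ion energy
#' from a Gaussian of the stated FWHM, draws the neutral's velocity vector
#' from a Maxwell-Boltzmann distribution at `t_neutral` and recomputes the
#' exact relative collision energy (Doppler broadening), draws vibrational
#' and rotational energies of both partners from Boltzmann distributions,
#' and evaluates the line-of-centers cross section. If a rate function is
#' supplied, each draw is weighted by the probability
#' \eqn{1 - e^{-k(E)\tau}} that the unimolecular step completes within the
#' detection window (kinetic shift). Returns per-grid-point means;
#' deterministic for a fixed seed.
#'
#' @param params A [loc_params()].
#' @param conditions A [beam_conditions()].
#' @param e_grid Nominal center-of-mass energies, eV (> 0, increasing).
#' @param n_samples Monte Carlo draws per grid point (>= 1).
#' @param seed Optional seed.
#' @param rate_fn Optional function `k(E)` (1/s) of the total available
#'   energy (relative translational + internal, eV) used for
#'   kinetic-shift weighting.
#' @return A [cross_section_curve()] whose `sigma_err_a2` column holds the
#'   Monte Carlo standard error of each mean.
#' @export
simulate_convolved_sigma <- function(params, conditions, e_grid,
                                     n_samples = 500, seed = NULL,
                                     rate_fn = NULL) {
  stopifnot(inherits(params, "loc_params"),
            inherits(conditions, "beam_conditions"))
  if (any(e_grid <= 0)) stop("`e_grid` must be > 0", call. = FALSE)
  if (n_samples < 1) stop("`n_samples` must be >= 1", call. = FALSE)
  cn <- conditions
  g <- length(e_grid)
  ntot <- g * n_samples
  sig <- with_seed(seed, {
    e_lab_nom <- rep(e_grid, each = n_samples) *
      (cn$m_ion + cn$m_neutral) / cn$m_neutral
    e_lab <- pmax(stats::rnorm(ntot, e_lab_nom,
                               cn$fwhm_lab * .const$fwhm_to_sd), 0)
    # velocities in sqrt(eV/amu) units; only energy ratios matter
    v_ion <- sqrt(2 * e_lab / cn$m_ion)
    sdv <- sqrt(.const$kb_ev * cn$t_neutral / cn$m_neutral)
    vx <- stats::rnorm(ntot, 0, sdv)
    vy <- stats::rnorm(ntot, 0, sdv)
    vz <- stats::rnorm(ntot, 0, sdv)
    mu <- reduced_mass(cn$m_ion, cn$m_neutral)
    e_rel <- 0.5 * mu * ((v_ion - vz)^2 + vx^2 + vy^2)
    e_vib <- sample_vib_energy(cn$ion_frequencies, cn$t_ion, ntot) +
      sample_vib_energy(cn$neutral_frequencies, cn$t_neutral, ntot)
    e_rot <- sample_rot_energy(cn$ion_rotor, cn$t_ion, ntot) +
      sample_rot_energy(cn$neutral_rotor, cn$t_neutral, ntot)
    excess <- e_rel + e_vib + e_rot - params$e0
    s <- ifelse(excess > 0 & e_rel > 1e-9,
                params$sigma0 * excess^params$n / pmax(e_rel, 1e-9), 0)
    if (!is.null(rate_fn)) {
      k <- rate_fn(e_rel + e_vib + e_rot)
      s <- s * (1 - exp(-pmax(k, 0) * cn$detection_window))
    }
    s
  })
  m <- matrix(sig, nrow = n_samples, ncol = g)
  means <- colMeans(m)
  ses <- apply(m, 2, stats::sd) / sqrt(n_samples)
  cross_section_curve(e_grid, means, ses)
}
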