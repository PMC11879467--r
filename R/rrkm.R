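#' Harmonic sums and densities of states by direct count
#'
#' Exact Beyer-Swinehart direct-count recursion for the sum \eqn{W(E)} and
#' density \eqn{\rho(E)} of harmonic vibrational states, with energies
#' measured above the zero-point level. Frequencies are rounded to the
#' nearest grain multiple; states landing in each grain bin are counted
#' exactly.
#'
#' @param frequencies Vibrational frequencies, cm^-1 (> 0).
#' @param grain Energy grain, cm^-1 (> 0). Default 10 cm^-1.
#' @param e_max Maximum energy of the count, cm^-1 (>= grain).
#' @return An object of class `state_count`: list with `grain_cm`,
#'   `energies_cm` (bin energies `0, grain, ...`), `counts` (states per
#'   bin), `sums` (cumulative \eqn{W(E)}), and `density_ev`
#'   (\eqn{\rho(E)}, states per eV).
#' @export
#' @examples
#' sc <- beyer_swinehart(c(100, 150, 300), grain = 10, e_max = 600)
#' sc$sums[sc$energies_cm == 600]
beyer_swinehart <- function(frequencies, grain = 10, e_max) {
  check_number(grain, "grain", 0, strict = TRUE)
  check_number(e_max, "e_max", grain)
  if (length(frequencies) == 0L || any(frequencies <= 0))
    stop("`frequencies` must be a non-empty vector of positive values",
         call. = FALSE)
  if (grain > min(frequencies))
    warning("grain exceeds the smallest frequency; state-count resolution ",
            "is degraded", call. = FALSE)
  m <- floor(e_max / grain)
  counts <- numeric(m + 1L)
  counts[1L] <- 1                      # the zero-point level
  for (f in frequencies) {
    fb <- max(1L, as.integer(round(f / grain)))
    if (fb > m) next
    for (i in seq.int(fb + 1L, m + 1L)) {
      counts[i] <- counts[i] + counts[i - fb]
    }
  }
  structure(list(
    grain_cm = grain,
    energies_cm = grain * (0:m),
    counts = counts,
    sums = cumsum(counts),
    density_ev = counts / (grain * .const$cm1_to_ev)
  ), class = "state_count")
}

#' @export
print.state_count <- function(x, ...) {
  cat(sprintf("<state_count> grain %g cm^-1, %d bins to %g cm^-1, W(max) = %g\n",
              x$grain_cm, length(x$counts), max(x$energies_cm),
              x$sums[length(x$sums)]))
  invisible(x)
}

state_bin <- function(sc, e_ev) {
  idx <- floor(e_ev / .const$cm1_to_ev / sc$grain_cm) + 1L
  if (any(idx > length(sc$counts)))
    stop("energy exceeds the state-count range; rebuild with a larger e_max",
         call. = FALSE)
  idx
}

# Density of states at e_ev (states/eV) averaged over a trailing window of
# `width_cm`: (W(E) - W(E - width)) / width. The windowed form gives a
# finite, convergent density even where a sparse discrete count leaves
# individual grain bins empty.
state_density <- function(sc, e_ev, width_cm) {
  s <- max(1L, as.integer(round(width_cm / sc$grain_cm)))
  bin <- state_bin(sc, e_ev)
  lo <- bin - s
  w_lo <- ifelse(lo >= 1L, sc$sums[pmax(lo, 1L)], 0)
  (sc$sums[bin] - w_lo) / (s * sc$grain_cm * .const$cm1_to_ev)
}

#' Reaction orbital angular momentum from the collision cross section
#'
#' \eqn{L = \mu v \sqrt{\sigma_{collision}/\pi} = \mu v b_{max}}: the
#' angular momentum at the maximum impact parameter implied by the
#' collision cross section.
#'
#' @param mu Reduced mass, amu (>= 0).
#' @param velocity Relative velocity, m/s (>= 0).
#' @param sigma_collision Collision cross section, Angstrom^2 (>= 0).
#' @return Angular momentum in SI units (kg m^2/s).
#' @export
orbital_L <- function(mu, velocity, sigma_collision) {
  check_number(mu, "mu", 0)
  if (any(velocity < 0) || any(sigma_collision < 0))
    stop("`velocity` and `sigma_collision` must be >= 0", call. = FALSE)
  mu * .const$amu_kg * velocity * sqrt(sigma_collision * 1e-20 / pi)
}

#' Centrifugal barrier of the orbiting transition state
#'
#' Maximum of the effective long-range ion/induced-dipole potential
#' \eqn{V(r) = -\alpha q^2 C / (2 r^4) + L^2/(2 \mu r^2)}, which is
#' \eqn{L^4 / (8 \alpha q^2 C \mu^2)} after unit normalization. This is
#' the threshold assigned to barrierless (orbiting-TS) channels.
#'
#' @param L Orbital angular momentum, SI (kg m^2/s), e.g. from
#'   [orbital_L()].
#' @param polarizability Neutral polarizability, Angstrom^3 (> 0).
#' @param charge Ion charge, elementary units (> 0).
#' @param mu Reduced mass, amu (> 0).
#' @return Barrier height in eV.
#' @export
centrifugal_barrier <- function(L, polarizability, charge = 1, mu) {
  check_number(polarizability, "polarizability", 0, strict = TRUE)
  check_number(charge, "charge", 0, strict = TRUE)
  check_number(mu, "mu", 0, strict = TRUE)
  if (any(L < 0)) stop("`L` must be >= 0", call. = FALSE)
  c4_j_m4 <- polarizability * charge^2 * .const$coulomb_ev_a *
    .const$ev_j * 1e-40                       # alpha q^2 C in J m^4
  mu_kg <- mu * .const$amu_kg
  (L^4 / (8 * c4_j_m4 * mu_kg^2)) / .const$ev_j
}

#' Microcanonical RRKM rate constant
#'
#' \eqn{k(E) = s \, W^{\ddagger}(E - E_0) / (h \rho(E))}: sum of states of
#' the transition state at the excess energy over the density of states of
#' the reactant at the total energy, with reaction path degeneracy `s`.
#' Returns 0 below threshold. The reactant density is evaluated as the
#' average \eqn{[W(E) - W(E - \Delta E)]/\Delta E} over a trailing window
#' `rho_width`, which keeps it finite and convergent for sparse discrete
#' counts; widen it for few-mode systems whose level ladders are coarser
#' than the default window.
#'
#' @param e Total internal energy above the reactant zero-point level, eV
#'   (vectorized, >= 0).
#' @param e0 Threshold (critical) energy, eV (>= 0).
#' @param reactant_count,ts_count [beyer_swinehart()] state counts for the
#'   reactant and the transition state, on the same grain.
#' @param symmetry Reaction path degeneracy (>= 1). Default 1.
#' @param rho_width Smoothing window for the reactant density of states,
#'   cm^-1 (> 0). Default 100 cm^-1.
#' @return Rate constants in 1/s.
#' @export
rrkm_k <- function(e, e0, reactant_count, ts_count, symmetry = 1,
                   rho_width = 100) {
  stopifnot(inherits(reactant_count, "state_count"),
            inherits(ts_count, "state_count"))
  check_number(e0, "e0", 0)
  check_number(symmetry, "symmetry", 1)
  if (any(e < 0)) stop("`e` must be >= 0", call. = FALSE)
  if (reactant_count$grain_cm != ts_count$grain_cm)
    stop("reactant and TS state counts must share the same grain",
         call. = FALSE)
  check_number(rho_width, "rho_width", 0, strict = TRUE)
  rho <- state_density(reactant_count, e, rho_width)
  if (any(rho == 0 & e >= e0))
    stop("reactant density of states is zero at a requested energy; ",
         "the energy is below the reactant zero-point level or the level ",
         "ladder is coarser than `rho_width`", call. = FALSE)
  k <- numeric(length(e))
  above <- e >= e0
  if (any(above)) {
    w <- ts_count$sums[state_bin(ts_count, e[above] - e0)]
    k[above] <- symmetry * w / (.const$h_ev_s * rho[above])
  }
  k
}

#' Kinetic isotope effect from rate-constant grids
#'
#' Pointwise ratio \eqn{k_{light}/k_{heavy}} on a common energy grid.
#' Points where the heavy rate is zero are returned as `NA` with a
#' warning (the ratio is undefined there).
#'
#' @param k_light,k_heavy Rate constants, 1/s, on the same grid.
#' @return Dimensionless ratio grid.
#' @export
kie_ratio <- function(k_light, k_heavy) {
  if (length(k_light) != length(k_heavy))
    stop("`k_light` and `k_heavy` must share a common energy grid",
         call. = FALSE)
  out <- ifelse(k_heavy == 0, NA_real_, k_light / k_heavy)
  if (anyNA(out))
    warning("KIE undefined where the heavy-isotopologue rate is zero",
            call. = FALSE)
  out
}

#' Wigner tunneling factor
#'
#' Lowest-order tunneling correction from the transition state's imaginary
#' frequency: \eqn{1 + (1/24)(h\nu^{\ddagger}/k_BT)^2}.
#'
#' @param imag_freq Magnitude of the imaginary frequency, cm^-1 (>= 0;
#'   vectorized).
#' @param T Temperature, K (> 0). Default 298 K.
#' @return Dimensionless factor >= 1.
#' @export
#' @examples
#' wigner_factor(c(169, 140, 857))
wigner_factor <- function(imag_freq, T = 298) {
  check_number(T, "T", 0, strict = TRUE)
  if (any(imag_freq < 0)) stop("`imag_freq` must be >= 0", call. = FALSE)
  1 + (imag_freq * .const$cm1_to_ev / (.const$kb_ev * T))^2 / 24
}

#' Statistical adduct populations from densities of states
#'
#' Fraction of population in each candidate isomer at total energy `E`,
#' proportional to its density of states:
#' \eqn{f_i = \rho_i(E) / \sum_j \rho_j(E)}.
#'
#' @param candidate_counts List of [beyer_swinehart()] state counts on a
#'   common grain.
#' @param e Total energy above each candidate's zero-point level, eV.
#' @param rho_width Density smoothing window, cm^-1, as in [rrkm_k()].
#' @return Numeric vector of fractions summing to 1 (named after the list
#'   names, if any).
#' @export
adduct_population <- function(candidate_counts, e, rho_width = 100) {
  stopifnot(length(candidate_counts) >= 1,
            all(vapply(candidate_counts, inherits, logical(1),
                       "state_count")))
  grains <- vapply(candidate_counts, function(x) x$grain_cm, numeric(1))
  if (length(unique(grains)) != 1L)
    stop("candidate state counts must share a common grain", call. = FALSE)
  check_number(e, "e", 0)
  check_number(rho_width, "rho_width", 0, strict = TRUE)
  d <- vapply(candidate_counts,
              function(sc) state_density(sc, e, rho_width), numeric(1))
  if (sum(d) == 0)
    stop("all candidate densities are zero at this energy", call. = FALSE)
  d / sum(d)
}

#' Detection (survival) probability within a time window
#'
#' Probability that a unimolecular step with rate constant `k` completes
#' within the instrument's detection window:
#' \eqn{1 - e^{-k\tau}}. This is the weighting behind the kinetic shift:
#' slow reactions near threshold are undercounted.
#'
#' @param k Rate constant, 1/s (>= 0; vectorized).
#' @param window Detection window, s (> 0). Default 1e-4 s.
#' @return Probability in [0, 1).
#' @export
#' @examples
#' survival_weight(1e4, 1e-4)   # 1 - exp(-1)
survival_weight <- function(k, window = 1e-4) {
  check_number(window, "window", 0, strict = TRUE)
  if (any(k < 0)) stop("`k` must be >= 0", call. = FALSE)
  -expm1(-k * window)
}
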