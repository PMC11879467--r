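# Shared fixtures and independent oracles, all built in code.

EV_PER_CM <- 1.239841984e-4
KB_EV <- 8.617333262e-5
H_EV_S <- 4.135667696e-15

# Exhaustive enumeration of harmonic states: number of occupation vectors
# (n_1, ..., n_m) with sum n_i * f_i <= e (cm^-1). Independent of the
# Beyer-Swinehart recursion.
count_states_brute <- function(freqs, e) {
  tot <- Reduce(function(acc, f) {
    as.vector(outer(acc, seq(0, floor((e + 1e-9) / f)) * f, "+"))
  }, freqs, 0)
  sum(tot <= e + 1e-9)
}

# States landing exactly at energy e (freqs chosen as grain multiples).
count_states_at_brute <- function(freqs, e) {
  tot <- Reduce(function(acc, f) {
    as.vector(outer(acc, seq(0, floor((e + 1e-9) / f)) * f, "+"))
  }, freqs, 0)
  sum(abs(tot - e) < 1e-6)
}

# Analytic orientation average of the projected area of a homonuclear
# diatomic: two disks of radius r whose projected center separation is
# d*sin(theta) for bond angle theta to the projection axis.
analytic_diatomic_area <- function(r, d) {
  f <- function(theta) {
    s <- d * sin(theta)
    overlap <- ifelse(
      s >= 2 * r, 0,
      2 * r^2 * acos(pmin(s / (2 * r), 1)) -
        (s / 2) * sqrt(pmax(4 * r^2 - s^2, 0)))
    (2 * pi * r^2 - overlap) * sin(theta)
  }
  stats::integrate(f, 0, pi / 2)$value
}

# Small paper-like beam setup shared across convolution/fit tests.
toy_beam <- function(fwhm = 0.65, t = 310, n_ion_modes = 51,
                     n_neutral_modes = 15) {
  ion <- gen_species(seed = 11, n_modes = n_ion_modes, mass = 165,
                     charge = 1L)
  neu <- gen_species(seed = 12, n_modes = n_neutral_modes, mass = 34)
  beam_conditions(m_ion = 165, m_neutral = 34, t_ion = t, t_neutral = t,
                  fwhm_lab = fwhm,
                  ion_frequencies = ion$frequencies,
                  neutral_frequencies = neu$frequencies)
}
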