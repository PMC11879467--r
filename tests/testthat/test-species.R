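test_that("XYZ files parse, reject malformed input, and round-trip", {
  f <- tempfile(fileext = ".xyz")
  writeLines(c("1", "", "C 0 0 0"), f)
  g <- read_xyz(f)
  expect_equal(g$element, "C")
  expect_equal(unlist(g[, c("x", "y", "z")], use.names = FALSE), c(0, 0, 0))

  writeLines(c("2", "count promises two atoms", "C 0 0 0"), f)
  expect_error(read_xyz(f), "parse error")
  writeLines(c("x", "", "C 0 0 0"), f)
  expect_error(read_xyz(f), "line 1")
  writeLines(c("1", "", "C 0 zero 0"), f)
  expect_error(read_xyz(f), "line 3")

  geom <- data.frame(element = c("N", "H", "H"),
                     x = c(0, 0.95, -0.47), y = c(0, 0, 0.82),
                     z = c(0.1, -0.3, 0.22))
  write_xyz(geom, f, comment = "round trip")
  back <- read_xyz(f)
  expect_equal(back$element, geom$element)
  expect_equal(as.matrix(back[, 2:4]), as.matrix(geom[, 2:4]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("zero-point energy is the scaled half-sum of mode energies", {
  expect_identical(zpe(numeric()), 0)
  expect_equal(zpe(1000, scale = 1), 0.06199, tolerance = 1e-4)
  expect_equal(zpe(1000), 0.975 * zpe(1000, scale = 1))
  expect_error(zpe(c(1000, -5)), "> 0")
  # additive over disjoint mode sets
  a <- c(120, 450, 900); b <- c(1600, 3100)
  expect_equal(zpe(c(a, b)), zpe(a) + zpe(b))
})

test_that("RRHO thermal correction has correct limits and hand value", {
  mode <- species("one-mode", mass = 20, frequencies = 207.2,
                  rotational_constants = c(1, 0.5, 0.4))
  # independent scalar arithmetic for the vibrational term at 298 K
  hv <- 207.2 * EV_PER_CM
  vib_expected <- hv / (exp(hv / (KB_EV * 298)) - 1)
  kt <- KB_EV * 298
  expect_equal(rrho_thermal_correction(mode, 298),
               vib_expected + 1.5 * kt + 1.5 * kt + kt, tolerance = 1e-10)
  # vibrational term vanishes at low T, leaving rotation+translation+PV
  expect_equal(rrho_thermal_correction(mode, 1e-6),
               4 * KB_EV * 1e-6, tolerance = 1e-12)
  atom <- species("Ar", mass = 40)
  expect_equal(rrho_thermal_correction(atom, 300), 2.5 * KB_EV * 300)
  expect_error(rrho_thermal_correction(atom, -1), "> 0")
  # additivity of the vibrational term over disjoint frequency sets
  ab <- species("ab", mass = 20, frequencies = c(207.2, 900))
  a <- species("a", mass = 20, frequencies = 207.2)
  b <- species("b", mass = 20, frequencies = 900)
  base <- species("none", mass = 20)
  expect_equal(rrho_thermal_correction(ab, 298) -
                 rrho_thermal_correction(base, 298),
               (rrho_thermal_correction(a, 298) -
                  rrho_thermal_correction(base, 298)) +
                 (rrho_thermal_correction(b, 298) -
                    rrho_thermal_correction(base, 298)))
})

test_that("spin projection extrapolates the BS/HS line to S^2 = 0", {
  expect_equal(spin_project(spin_pair(-5, -5, 0.4, 2.1)), -5)
  expect_equal(spin_project(spin_pair(-5.0, -4.0, 0, 2)), -5.0)
  expect_equal(spin_project(spin_pair(-1.0, -0.9, 1.0, 2.0)), -1.1)
  # line through the two points, evaluated at S^2 = 0
  p <- spin_pair(-2.3, -1.7, 0.8, 2.2)
  slope <- (p$E_HS - p$E_BS) / (p$S2_HS - p$S2_BS)
  expect_equal(spin_project(p), p$E_BS - slope * p$S2_BS)
  expect_error(spin_pair(-1, -1, 1, 1), "S2_HS > S2_BS")
})

test_that("thermochemical cycles are antisymmetric differences", {
  expect_equal(ct_endothermicity(9.04, 7.63), 1.41)
  expect_equal(ct_endothermicity(7.63, 9.04), -1.41)
  expect_equal(ct_endothermicity(5, 5), 0)
  expect_equal(pt_threshold(9.9, 9.32), 0.58)
  expect_equal(pt_threshold(10.1, 9.32), 0.78)
  expect_equal(pt_threshold(7, 7), 0)
  expect_equal(pt_threshold(9.9, 9.32), -pt_threshold(9.32, 9.9))
})

test_that("reaction enthalpy sums per-species terms and conserves", {
  a <- species("A", mass = 30, frequencies = c(500, 1500),
               rotational_constants = c(2, 1, 0.8),
               electronic_energy = 0, energy_ref = "r1")
  b <- species("B", mass = 17, frequencies = 900,
               rotational_constants = 12,
               electronic_energy = -0.4, energy_ref = "r1")
  expect_equal(reaction_enthalpy(list(a, b), list(a, b)), 0)
  # hand evaluation: difference of electronic + scaled ZPE + thermal terms
  h <- function(s, T = 298.15) {
    s$electronic_energy + zpe(s$frequencies) +
      rrho_thermal_correction(s, T)
  }
  expect_equal(reaction_enthalpy(list(a), list(b)), h(b) - h(a))
  # forward plus reverse cancels
  expect_equal(reaction_enthalpy(list(a), list(b)) +
                 reaction_enthalpy(list(b), list(a)), 0)
  bad <- species("C", mass = 10, frequencies = 100,
                 electronic_energy = 1, energy_ref = "other")
  expect_error(reaction_enthalpy(list(a), list(bad)), "references")
  nofreq <- species("D", mass = 10)
  expect_error(reaction_enthalpy(list(a), list(nofreq)),
               "electronic_energy")
})

test_that("species validation enforces invariants", {
  expect_error(species("x", mass = -1), "mass")
  expect_error(species("x", mass = 1, frequencies = c(100, 0)), "> 0")
  expect_error(species("x", mass = 1, symmetry_number = 0), ">= 1")
  expect_equal(rotor_type(species("a", 1)), "atom")
  expect_equal(rotor_type(species("l", 1, rotational_constants = 2)),
               "linear")
  expect_equal(rotor_type(species("l2", 1,
                                  rotational_constants = c(2, 2))),
               "linear")
  expect_equal(rotor_type(species("n", 1,
                                  rotational_constants = c(3, 2, 1))),
               "nonlinear")
})
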