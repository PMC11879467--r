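---
title: "Threshold energies and statistical kinetics for ion-molecule reactions"
author: "gibkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold energies and statistical kinetics for ion-molecule reactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gibkin)
```

## The scientific problem

Oxidatively damaged guanine is the main entry point for DNA-protein
crosslinks: one-electron oxidation produces the 9-methylguanine radical
cation (9MG^•+^, m/z 165) and a second oxidation its deprotonated
closed-shell counterpart ([9MG - H]^+^, m/z 164). In a guided-ion-beam
experiment these cations collide with a lysine-mimicking amine
(methylamine, deuterated to m/z 34) under single-collision conditions,
and the energy dependence of each product channel's cross section
carries the reaction thermochemistry and mechanism. gibkin implements
the full analysis chain around such measurements: absolute cross
sections, collision models, the threshold law and its broadening, and
the statistical (RRKM) kinetics of the collision complexes.

All energetics are carried in eV, frequencies in cm^-1^, masses in amu,
lengths in Angstrom (`kin_constants()` centralizes the conversions).

## Kinematics and absolute cross sections

A beam ion of lab-frame energy $E_{lab}$ striking an effectively
stationary neutral of mass $m_n$ has center-of-mass collision energy
$E_{CM} = E_{lab}\, m_n/(m_i + m_n)$ (`ecm_from_elab()`). The same
projection applied to the lab-frame energy FWHM ($\le 0.65$ eV for the
modeled beam) gives the nominal $E_{CM}$ spread, about 0.1 eV for the
165/34 amu pair.

Product cross sections follow from beam attenuation through the
Beer-Lambert law (`beer_lambert_sigma()`), with the target number
density from the ideal-gas law at the cell pressure (0.01-0.015 mTorr)
and the 11 cm effective path. At these pressures attenuation is far
below 1%, so the default thin-target form and the exact logarithmic
form agree to better than 1%; both are provided. The cell temperature
entering the density is not separately measured, so it defaults to the
310 K ion-thermalization temperature and is configurable.

## Collision and capture models

Reaction efficiency is $\sigma_{total}/\sigma_{collision}$ where
$\sigma_{collision}$ is the larger of a capture cross section and a
hard-sphere cross section (`collision_sigma()`).

* **Capture.** The Langevin ion/induced-dipole form
  $\sigma_L = \pi\sqrt{2\alpha q^2 C/E}$ is exact for a nonpolar
  neutral. For a polar neutral the package uses the Su-Chesnavich
  trajectory parametrization: a dimensionless dipole parameter
  $x = \mu_D\sqrt{C/(2\alpha k_B T)}$ sets a multiplicative enhancement
  $K(x)$ over Langevin. This closed-form choice brackets the physically
  locked-dipole and free-rotor limits and reduces to Langevin as the
  dipole vanishes (the published constants reproduce $K(0) = 1$ to
  about $10^{-5}$; the exact zero-dipole case is special-cased).
  Langevin and locked-dipole are selectable alternatives.
* **Hard sphere.** Each partner's orientation-averaged projected area
  is estimated by Monte Carlo: uniform random rotations (uniform
  quaternion sampling) and, within each orientation, uniform point
  sampling in a fixed bounding disk to measure the union-of-disks area.
  This is unbiased for arbitrary overlap topology and exact (by
  shortcut) for a single atom; the standard error, reported as an
  attribute, scales as $1/\sqrt{n_{orientations}}$. Effective radii
  $r = \sqrt{A/\pi}$ combine as $\sigma_{hs} = \pi(r_a + r_b)^2$; the
  combination rule is isolated in `projected_area_sigma()` so it can be
  swapped. Atomic radii default to the bundled Bondi table and are
  user-overridable.

## The threshold law and its broadening

Endothermic channels are fitted with the modified line-of-centers
model

$$\sigma(E_{CM}) = \sigma_0\,
  \frac{(E_{CM} + E_{vib} + E_{rot} - E_0)^n}{E_{CM}},$$

where $E_0$ is the 0 K threshold and $n$ measures how efficiently
translational energy drives the reaction (best fits in the modeled
study fall at $n = 2.4$-$2.5$, the package default starting point).
Reactant internal energy counts fully toward the threshold.

A measured onset never looks like the bare law, so
`simulate_convolved_sigma()` embeds it in a Monte Carlo convolution
that samples, per draw:

1. the lab-frame ion energy from a Gaussian with the stated FWHM
   (FWHM/SD factor 2.3548; the true beam shape is not reported, and a
   Gaussian is the conventional choice),
2. the neutral's full velocity vector from a Maxwell-Boltzmann
   distribution, recomputing the exact relative collision energy — this
   realizes Doppler broadening without an analytic width approximation
   and unifies it with the beam-spread sampling,
3. vibrational energies of both partners per mode from the quantum
   Boltzmann distribution over harmonic levels, and classical
   rotational energies (2 or 3 degrees of freedom),
4. optionally, a detection weight $1 - e^{-k(E)\tau}$ when a rate
   function is supplied: slow unimolecular steps near threshold do not
   complete within the instrument's $\tau \approx 10^{-4}$ s time of
   flight, producing the kinetic shift.

Two temperatures are deliberately distinct: reaction enthalpies use
298.15 K by convention, while beam internal energies default to the
310 K thermalization temperature of the ion source.

`fit_threshold()` minimizes weighted least squares ($1/\sigma_{err}^2$
when uncertainties are supplied, else uniform) between the convolved
model and the data. $\sigma_0$ enters linearly and is profiled out
analytically; $E_0$ is found by 1-D minimization at each exponent on an
`n` scan grid (0.1 steps). Every objective evaluation reuses the same
random stream, so the objective is smooth and deterministic. The $E_0$
uncertainty is reported in three parts: half the $E_0$ spread across
acceptable exponents (objective within 10% of the minimum — the
acceptability criterion is a package choice, as no standard exists),
the $E_{CM}$ Gaussian SD implied by the lab FWHM, and their quadrature
combination (whether these components should combine in quadrature or
additively is not established; both pieces are exposed so either
convention can be applied).

```{r fit-example, eval = FALSE}
ion <- gen_species(seed = 11, n_modes = 51, mass = 165, charge = 1)
amine <- gen_species(seed = 12, n_modes = 15, mass = 34)
cond <- beam_conditions(m_ion = 165, m_neutral = 34,
                        ion_frequencies = ion$frequencies,
                        neutral_frequencies = amine$frequencies)
truth <- loc_params(sigma0 = 2, e0 = 1.5, n = 2.4)
curve <- gen_curve(truth, cond, seq(0.8, 2.0, 0.05),
                   noise_cv = 0.05, n_samples = 600, seed = 101)
fit_threshold(curve, cond, n_range = 2.4, seed = 7,
              e0_bounds = c(0.9, 1.9))
```

## Statistical kinetics

`beyer_swinehart()` performs the exact direct-count recursion for
harmonic sums and densities of states (energies above the zero-point
level; default grain 10 cm^-1^, with a warning when the grain exceeds
the smallest frequency). The microcanonical rate constant is

$$k(E) = \frac{s\,W^{\ddagger}(E - E_0)}{h\,\rho(E)},$$

with reaction path degeneracy $s$ defaulting to 1. Because a strict
harmonic count is a Dirac comb, $\rho(E)$ is evaluated as the average
$[W(E) - W(E-\Delta E)]/\Delta E$ over a trailing window (default
100 cm^-1^, exposed as `rho_width`); for realistic mode counts the
choice is immaterial, while few-mode toy systems need a window wider
than their level spacing. Halving the grain changes $k$ by under 2% for
the shipped examples.

Barrierless association channels get an orbiting transition state: the
orbital angular momentum is taken from the collision cross section as
$L = \mu v \sqrt{\sigma_{collision}/\pi}$ at the nominal $E_{CM}$
(`orbital_L()`), and the channel threshold is the centrifugal barrier
of the ion/induced-dipole potential, $L^4/(8\alpha q^2 C \mu^2)$
(`centrifugal_barrier()`). Setting that barrier equal to $E_{CM}$
recovers the Langevin cross section in closed form, which the test
suite uses to validate the whole unit chain to $10^{-6}$ relative.

Isotope effects are pointwise rate ratios on a common energy grid
(`kie_ratio()`), tunneling uses the Wigner factor
$1 + \frac{1}{24}(h\nu^{\ddagger}/k_BT)^2$ at 298 K by default (the
evaluation temperature is not stated for the reported factors; 298 and
310 K round identically for all three printed frequencies), and
competing adduct isomers are populated in proportion to their densities
of states (`adduct_population()`). The reported crosslinking rate
constants ($8\times10^8$-$3\times10^9$ s^-1^) and $k_H/k_D = 4$-$5$
require the study's optimized frequency sets, which are not published
as machine-readable data; the same machinery accepts user-supplied
frequency files (`read_frequencies()`, the `rrkm` and `kie` pipeline
stages) as an optional validation path.

Diradical energetics use Yamaguchi approximate spin projection
(`spin_project()`), which is exactly the line through the
broken-symmetry and high-spin points evaluated at
$\langle S^2 \rangle = 0$. Thermochemical thresholds for charge and
proton transfer come from tabulated ionization potentials and
acidity/basicity values (`ct_endothermicity()`, `pt_threshold()`);
whether the tabulated acidities are 0 K or 298 K quantities is not
recorded with them, so they are used as supplied.

## What the synthetic data emulate — and what they do not

No measured cross-section tables are distributed with the study this
package models (curves exist only as figures, which the package never
digitizes), so the synthetic module is the test surface.
`gen_species()` builds reproducible toy molecules with frequencies in
the organic range (50-3500 cm^-1^) and mass-scaled rotational
constants; `gen_isotopologue()` lowers selected modes (default
$1/\sqrt2$, the harmonic H/D stretch limit); `gen_curve()` runs the
full convolution under the beam conditions and adds multiplicative
Gaussian noise, with the uncertainty column floored at 5% of the curve
maximum so below-threshold points keep a finite detection-noise level.
All generators are bit-reproducible under a fixed seed.

The recovery study shipped in the test suite generates curves under the
study conditions — 310 K, 0.65 eV lab FWHM, 165/34 amu, $n = 2.4$, 5%
noise — on a 0.8-2.0 eV grid (25 points, 600 draws per point) and
refits them (300 draws per evaluation, 20 replicates); the median
absolute $E_0$ error is well inside 0.05 eV. What this shows is that
the estimator is unbiased and precise when the model matches the data;
it cannot show robustness to real-world model error (non-Gaussian beam
shapes, channel competition, drifting detection efficiency), which is
why experimental thresholds carry the larger 0.1-0.2 eV uncertainties.
Single-channel fits only: competing channels are fitted independently,
as is standard for this experiment class.

## Degenerate inputs and numerical edges

* `loc_sigma()` is continuous at threshold for any $n > 0$ (infinite
  slope for $n < 1$); the convolution guards the $1/E_{CM}$ divergence
  with a $10^{-9}$ eV floor, far below any realistic grid.
* Fits refuse all-zero curves and fewer than 5 points; a model that is
  identically zero over the data grid contributes its full weighted
  norm, steering the search back.
* State-count lookups beyond the built table raise an error rather
  than extrapolate; rebuild with a larger `e_max`.
* The projected-area estimator returns an exact $\pi r^2$ (zero SE)
  for single atoms, keeping sphere-only uses deterministic.

## Reproducibility

Every stochastic routine takes an explicit seed and restores the
caller's RNG state. `run_pipeline()` echoes the full configuration, its
hash, the seed and the package version into `summary.json`; reruns with
the same configuration are byte-identical. Stages write tab-separated
tables whose headers name the units.
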