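---
title: "Modelling powder IR/THz absorption with powderspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling powder IR/THz absorption with powderspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(powderspec)
```

## The problem

Infrared and terahertz spectra of crystalline powders are routinely measured
on finely ground material dispersed in a non-absorbing support (PTFE, KBr,
Nujol, polyethylene). For ionic and strongly polar crystals the measured band
positions are *not* the transverse-optic (TO) phonon frequencies that a
gamma-point lattice-dynamics calculation delivers: the polarization of each
small particle couples the phonons to the internal electric field, shifting
absorption up towards (and between) the longitudinal-optic (LO) frequencies
by an amount that depends on particle shape, on the loading, and on the
permittivity of the support. `powderspec` models this chain quantitatively,
starting from gamma-point phonon frequencies, mode eigenvectors, Born
effective charges and the optical (electronic) permittivity.

The pipeline is

1. **Lorentz-oscillator permittivity.** Each mode $k$ has a charge vector
   $\bar Z_k = \sum_a \bar{\bar Z}_a \bar U_{ka}/\sqrt{m_a}$ (Born charge
   tensor times the mass-weighted eigenvector, per root mass) and an
   oscillator-strength tensor $\bar{\bar S}_k = \bar Z_k \bar Z_k^T$.  The
   complex permittivity tensor is
   $$\bar{\bar\varepsilon}(\bar\nu) = \bar{\bar\varepsilon}_\infty +
     \frac{\gamma}{V}\sum_k
     \frac{\bar{\bar S}_k}{\nu_k^2 - \bar\nu^2 - i\sigma_k\bar\nu}$$
   with $V$ the cell volume and $\gamma$ a units constant (below).
2. **Particle response.** A particle of permittivity
   $\bar{\bar\varepsilon}_i$ and depolarization tensor $\bar{\bar L}$ in a
   matrix of scalar permittivity $\varepsilon_e$ has polarizability
   $\bar{\bar\alpha} = V\varepsilon_e(\bar{\bar\varepsilon}_i -
   \varepsilon_e\bar{\bar 1})(\varepsilon_e\bar{\bar 1} +
   \bar{\bar L}(\bar{\bar\varepsilon}_i - \varepsilon_e\bar{\bar 1}))^{-1}$.
3. **Homogenization.** Maxwell-Garnett, Bruggeman, or the shape-free
   averaged-permittivity rule turn the single-particle response into one
   isotropic effective permittivity per frequency.
4. **Spectra.** The physical branch of
   $N = \sqrt{\varepsilon_{\rm eff}}$ ($\kappa \ge 0$) gives the decadic
   absorption coefficient $\alpha = 4\pi\bar\nu\kappa\log_{10}e$ and, with
   the concentration of unit cells
   $C = f\cdot 1000/(V\cdot 10^{-24} N_A)$ mol/L, the molar absorption
   coefficient $a = \alpha/C$.

Everything operates at wavelengths much longer than the particle size;
scattering by large particles and phonon-polariton coupling are outside the
model, as is particle agglomeration at high loading.

## Units, and one constant

All frequencies are wavenumbers (cm⁻¹), volumes Å³, Born charges in units of
the elementary charge, and intensities (traces of
$\bar{\bar S}_k$) in (D/Å)²/amu.  Everything that connects them is derived
at run time from CODATA constants in `unit_constants()`:

```{r}
str(unit_constants())
```

`gamma_eps` (≈ 2.133·10⁶) makes one oscillator contribute
`gamma_eps * S/(V * nu^2)` to the permittivity; its value is pinned
independently by the static permittivity of cubic MgO, whose single
triply-degenerate TO band at 388.3 cm⁻¹ with intensity 9.29 (D/Å)²/amu and
$\varepsilon_\infty = 3.14$ must (and does) yield a static permittivity of
10.0.  `molar_absorption_unit` (≈ 4225.6 L mol⁻¹cm⁻² per intensity unit,
i.e. 42.256 km/mol) is the bridge between a transition intensity and the
integrated molar absorption coefficient.  The commonly printed closed form
for this constant carries a spurious $1/\ln 10$; the value 4225.6 itself,
and the km/mol equivalence, correspond to $N_A\pi/(3000c^2)$ applied to an
intensity in (D/Å)²/amu, and that is what the package computes.

### Eigenvector convention

Eigenvectors are those of the mass-weighted dynamical matrix: dimensionless
and orthonormal, with physical displacements proportional to
$U_{ka}/\sqrt{m_a}$.  The mode-charge formula above therefore divides by
$\sqrt{m_a}$; this is forced by the intensity unit (per amu) and verified by
the Lyddane-Sachs-Teller (LST) relation, which the implementation reproduces
to 10⁻⁶ on synthetic single-oscillator crystals.  Files that store Cartesian
displacement vectors instead declare `eigenvector_convention: cartesian` and
are converted (and re-normalized) at read time.

## The phonon-data file

`read_phonon_data()`/`write_phonon_data()` use a versioned YAML schema
(`format: powderspec-phonon v1`) holding lattice vectors (Å), atoms
(label, mass, 3×3 Born charge tensor), 3N frequencies (negative = imaginary),
3N orthonormal eigenvectors and the 3×3 optical permittivity.  YAML was
chosen because the schema is plain key/value plus arrays, comments and blank
lines are tolerated natively, and round trips preserve doubles exactly at
precision 17.  Validation enforces the 3N count, orthonormality to 10⁻⁶,
symmetry of $\varepsilon_\infty$ and diagonal entries ≥ 1.

## LO frequencies

`lo_frequencies()` rebuilds the dynamical matrix as
$D = U^T\,\mathrm{diag}(\mathrm{sign}(\nu)\nu^2)\,U$ (the only route
available when a file stores frequencies and eigenvectors rather than force
constants) and adds the long-wavelength non-analytic correction for an
approach direction $\hat q$,
$$\Delta D_{s\alpha,t\beta} = \frac{\gamma'}{V}\,
  \frac{(\hat q^T\bar{\bar Z}_s)_\alpha(\hat q^T\bar{\bar Z}_t)_\beta}
       {\sqrt{M_sM_t}\,(\hat q^T\bar{\bar\varepsilon}_\infty\hat q)},$$
using the *optical* permittivity in the screening denominator — the choice
required for the LST limit to hold exactly — and the same unit bridge as the
permittivity.  The result is invariant under $q \to -q$ and $q \to 2q$.

## Particle shapes

The unique axis of a needle or ellipsoid is the direct-lattice direction
[hkl]; a plate's unique axis is the *normal* to the plane (hkl), i.e. the
reciprocal-lattice vector — these differ in non-orthogonal cells and the
distinction is tested against a metric-tensor computation.  Depolarization
tensors: sphere $\bar{\bar 1}/3$; plate $\bar V_1\bar V_1^T$; needle
$(\bar V_2\bar V_2^T + \bar V_3\bar V_3^T)/2$; spheroid
$a\bar V_1\bar V_1^T + b(\bar V_2\bar V_2^T+\bar V_3\bar V_3^T)$ with the
prolate/oblate closed forms in `spheroid_depolarization_factors()`.  The
ellipsoid parameter `z` is read as the aspect ratio (unique-axis length over
perpendicular length), the reading consistent with describing an elongated
habit by "aspect ratio 2"; $z\to\infty$ tends to the needle and $z\to 0$ to
the plate, with $a(z)$ continuous and monotone through $z = 1$.  The
perpendicular axes $\bar V_2,\bar V_3$ are completed deterministically
(pivot on the smallest component of $\bar V_1$) purely so outputs are
reproducible; results are provably independent of the completion and a test
randomizes it.

## Mixing rules and their numerical choices

Orientational averaging over uniformly random particle alignments is done
analytically: $\langle\bar{\bar\alpha}\rangle =
\mathrm{tr}(\bar{\bar\alpha})/3$ and likewise for
$\langle\bar{\bar\alpha}\bar{\bar L}\rangle$ (both tensors co-rotate).  A
Monte-Carlo rotation test confirms the identity.

**Maxwell-Garnett** is implemented as
$\varepsilon_{mg} = \varepsilon_e + n\langle\alpha\rangle/
(1 - n\langle\alpha L\rangle/\varepsilon_e)$ with $n = f/V$, the form that
satisfies $\varepsilon_{mg}(f{=}0) = \varepsilon_e$ and reduces exactly to
the textbook scalar formula for isotropic spheres (asserted to 10⁻¹⁰).

**Bruggeman** treats both phases symmetrically against the effective
medium, sharing one depolarization tensor (appropriate only when both
phases have similar morphology — a known limitation).  The self-consistent
scalar condition is solved per frequency by fixed-point iteration of
$$\varepsilon_{br} \leftarrow
 \frac{f_1\langle\varepsilon_1 A_1^{-1}\rangle +
       f_2\langle\varepsilon_2 A_2^{-1}\rangle}
      {f_1\langle A_1^{-1}\rangle + f_2\langle A_2^{-1}\rangle},\qquad
 A_i = \varepsilon_{br}\bar{\bar 1} +
       \bar{\bar L}(\bar{\bar\varepsilon}_i - \varepsilon_{br}\bar{\bar 1}),$$
whose bracket uses $\varepsilon_{br}\bar{\bar 1}$ (dimensional consistency
and the dilute-limit agreement with Maxwell-Garnett require it).  Seeding is
the Maxwell-Garnett value at the first grid point and the previous
frequency's solution thereafter; convergence is a relative change below
10⁻⁸ with a cap of 1000 sweeps (engineering choices, exposed as arguments).
A converged root with negative imaginary part is retried from the
Maxwell-Garnett seed and otherwise flagged — Bruggeman solutions are known
to go unphysical when the real parts of the two permittivities differ in
sign, and flags are never silently dropped.  Close to the Fröhlich
resonance of a dilute sphere the Bruggeman-vs-MG deviation, measured
relative to the (small) contrast $|\varepsilon_{mg}-\varepsilon_e|$, is
first order in $f$ but resonance-amplified; measured relative to the
permittivity itself the two rules agree to 0.1% at $f = 10^{-4}$.

**Averaged permittivity** ($f\langle\varepsilon_i\rangle + (1-f)
\varepsilon_e$) ignores shape entirely and peaks at the TO frequencies at
low loading; it is the baseline against which shape shifts are read.

## Degenerate bands in oscillator tables

Reduced "oscillator-table" inputs (frequency, symmetry label, intensity,
$\varepsilon_\infty$ diagonal, cell) are expanded by
`from_oscillator_table()`.  A non-degenerate `A` band is polarized along the
unique axis; a doubly degenerate `E` band contributes its printed intensity
**per partner**, one partner on each perpendicular axis; a `T` band puts its
printed intensity on each of the three axes.  The per-partner reading is
adopted because it reproduces both the isotropic MgO static permittivity
(10.0 from a printed intensity of 9.29) and the published calcite sphere
shifts (732 → ≈786 cm⁻¹ and 1464 → ≈1480 cm⁻¹); the alternative
shared-intensity reading is available via `shared_intensity = TRUE` for
sensitivity checks.  Reconstructed static permittivities for calcite miss
the published values by ≈5%, consistent with weak bands omitted from the
printed table; this is reported, not corrected.

```{r}
mgo <- from_oscillator_table(reference_models()$mgo, sigma = 10)
glance(mgo)
```

## A worked example

Ten percent by volume of MgO spheres in a matrix of permittivity 2
(PTFE-like), damping 10 cm⁻¹:

```{r}
sc <- mixing_scenario("maxwell", volume_fraction = 0.1,
                      matrix_permittivity = 2,
                      shape = depolarization(shape_spec("sphere")),
                      inclusion_volume = mgo$cell_volume)
sp <- powder_spectrum(mgo, sc, spectral_grid(300, 800, 0.2))
find_spectrum_peaks(sp)
```

The single TO band at 388.3 cm⁻¹ appears shifted by roughly 150 cm⁻¹
towards the LO frequency (693 cm⁻¹), the hallmark of the internal-field
coupling in small dielectric spheres; in the dilute, lightly damped limit
the peak converges to the Fröhlich frequency
$\nu_{TO}\sqrt{(\varepsilon_s + 2\varepsilon_e)/(\varepsilon_\infty +
2\varepsilon_e)}$, and for $\varepsilon_e = 1$ it lies strictly between TO
and LO.

Peak positions are refined by quadratic interpolation through the three
points around each grid maximum, since published positions are quoted finer
than typical grid steps; halving the grid increment moves no reported peak
by more than one coarse step.

## The synthetic-crystal generator

`make_toy_crystal()` produces random but structurally valid inputs:
orthonormal eigenvector sets containing the three exact translational modes,
Born charges satisfying the acoustic sum rule (so the translations carry
zero oscillator strength by construction), a mildly anisotropic cell and a
symmetric positive-definite $\varepsilon_\infty$, all deterministic under a
seed.  `single_oscillator_crystal()` builds a two-atom cubic crystal whose
isotropic Born charge is derived from a requested per-axis intensity — the
analytic reference for LST and Fröhlich checks (for MgO-like parameters the
derived charge, ±1.97 e, is physically sensible).

What the generator does **not** emulate: real space-group symmetry and the
degeneracy patterns it forces, realistic LO-TO orderings in multi-band
crystals, frequency-dependent (anharmonic) damping, and correlated
intensity/frequency distributions of real materials.  Passing tests on
generated data therefore validate the algebra and the invariants
(orthonormality handling, sum rules, round trips), not the package's
agreement with any particular material — that is what the reference-model
checks are for.

## Problem sizes and tolerances in the shipped tests

The test-suite uses small problems chosen for sharpness rather than realism:
toy crystals of 2-6 atoms, grids of a few hundred to a few thousand points
(step 0.1-5 cm⁻¹), 10⁴ Monte-Carlo rotations for the averaging oracle, and
dampings of 1-10 cm⁻¹.  Structural identities (trace of the depolarization
tensor, round trips, closed-form polarizabilities) are asserted at 10⁻¹⁰ to
10⁻¹²; physics reproductions (static permittivities, LO positions, peak
shifts) at the precision to which the underlying inputs are quoted.

## Known limitations

* Only spheroidal particles (two equal semi-axes); no triaxial ellipsoids,
  coated particles, multi-shape mixtures, or percolation-aware rules.
* Constant damping per mode; no anharmonic line-shape models.
* The aspartic-acid reference model lacks directional band assignments and
  is suitable for smoke tests only.
* No parsers for the native output of specific lattice-dynamics codes; data
  enter through the documented canonical format.
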