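---
title: "Modelling excitons in double-walled tubular dye aggregates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling excitons in double-walled tubular dye aggregates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excitube)
```

## The system and the modelling strategy

Amphiphilic cyanine dyes such as C8S3 self-assemble in water into
double-walled nanotubes: two coaxial cylinders of close-packed chromophores
(inner-wall radius ≈ 3.2 nm, outer ≈ 6.5 nm by cryo-TEM, with a wall-to-wall
distance near 2.5 nm in stable packings), tens of thousands of molecules
long.  They are popular mimics of chlorosomal antenna complexes because
their absorption is dominated by strongly red-shifted, axially polarized
J-bands — the signature of Frenkel excitons delocalized over hundreds of
molecules.  The spectrum cannot be predicted from any single technique: the
molecular packing is below imaging resolution, and the optics depend
sensitively on that packing.

`excitube` implements the modelling chain that connects a *hypothesised*
packing to an *observable* spectrum:

1. build a two-dimensional herringbone lattice (two molecules per unit
   cell) and roll it onto one or two coaxial cylinders;
2. translate the geometry into a Frenkel exciton Hamiltonian with
   extended-dipole couplings;
3. perturb the structure and the site energies with disorder models that
   stand in for molecular-dynamics sampling and microelectrostatic
   environment calculations;
4. diagonalize, form collective transition dipoles, and average
   polarization- and wall-resolved absorption spectra over the disorder
   ensemble;
5. compare structural hypotheses through diagnostics (pair angle–distance
   maps, per-site coupling sums) and parameter scans (rolling angle,
   packing density).

## Lattice construction and rolling

A `unit_cell()` holds lattice vectors $a_1, a_2$ (nm) and a two-molecule
basis with fractional positions, in-plane dipole angles (the herringbone
pair, measured from $a_1$) and out-of-plane tilts.  Rolling wraps the plane
onto a cylinder of radius $r$ so that the planar coordinate $u$ along the
rolling direction becomes the azimuth $\phi = u/r$ (arc length is
preserved) and the transverse coordinate becomes $z$.  Dipoles are carried
rigidly by the local frame: a planar dipole with (circumferential, axial,
normal) components $(d_c, d_t, d_n)$ becomes
$d_c(-\sin\phi, \cos\phi, 0) + d_t(0,0,1) + d_n(\cos\phi, \sin\phi, 0)$.

A seamless wrap requires the circumference vector to be a lattice
translation $m_1 a_1 + m_2 a_2$, exactly as for a carbon-nanotube chiral
vector.  `commensurate_rolling()` therefore snaps the requested
$(r, \theta)$ to the nearest such vector, *adjusting the radius* (by at
most 2% by default) and the rolling angle (by at most 4°) while leaving
the lattice itself unstrained.  The experimental radii carry ±0.5 nm error
bars, so a ≤2% radius nudge is well inside the physics; straining the
lattice instead would corrupt the couplings, which depend on it far more
strongly.  Sites occupy the half-open azimuthal interval $[0°, 360°)$ — no
duplicated seam row — and tubes have open ends at $z \in [0, L]$.

**Open versus screw-periodic ends.**  Finite open tubes are the default
and are what the disorder machinery uses.  For *band-structure* questions
(where does the parallel peak of an ideal lattice sit?) open ends are a
nuisance: edge sites lose their most strongly coupled neighbours
anisotropically, and at $N \approx 1000$ this drags the apparent parallel
peak by ~100 cm⁻¹ as the rolling angle turns.  `build_tube(axial =
"periodic")` instead snaps the axial extent to a lattice translation $T$
and records the screw operation (axial period plus twist
$\Delta\phi = (T \cdot \hat c)/r$); with `build_hamiltonian(periodic =
TRUE)` every site is coupled to the screw images of all sites (±2 periods),
which reproduces the exact infinite-tube environment of every molecule.
All ideal-tube scans use this mode; with it the parallel peak moves by
< 5 cm⁻¹ across rolling angles 20–55° while the perpendicular peak moves by
~800 cm⁻¹.

## The exciton Hamiltonian

The one-exciton Hamiltonian in the site basis is
$$H_{nn} = E_0 + \Delta\varepsilon_n, \qquad
  H_{nm} = J_{nm} \;(n \neq m),$$
with $E_0 = 19\,498$ cm⁻¹ the gas-phase monomer excitation energy used to
anchor the absolute spectral position, and $\Delta\varepsilon_n$ an
environment shift.  Couplings use the extended-dipole model: each
transition dipole is two charges $\pm q$ separated by $l$ along the dipole
axis (on a cyanine, the polymethine bridge), and
$$J_{nm} = \frac{k\,q^2}{s}\left[\frac{1}{r_{++}} + \frac{1}{r_{--}}
  - \frac{1}{r_{+-}} - \frac{1}{r_{-+}}\right],$$
with $k = e^2/(4\pi\varepsilon_0 h c) = 1.1614 \times 10^4$
cm⁻¹ nm e⁻² (from CODATA constants: $e^2/4\pi\varepsilon_0 =
1.439964548$ eV nm and 1 eV $= 8065.544$ cm⁻¹) and $s$ an optional
relative screening constant (default 1, vacuum — no medium screening is
assumed for the resonance couplings).  Side-by-side parallel dipoles give
$J > 0$ (H-type), head-to-tail $J < 0$ (J-type); beyond ~20 dipole lengths
the kernel agrees with the point-dipole formula to better than 0.5%.  A
0.1 nm guard between charge end points of different molecules rejects
unphysical overlaps.

Diagonalization is a full dense symmetric decomposition (no sparse path;
$N \lesssim 10^4$ fits comfortably in memory).  Each state gets a
collective dipole $\vec\mu_k = \sum_n c_{kn}\,\mu\,\hat d_n$; oscillator
strength obeys the sum rule $\sum_k |\vec\mu_k|^2 = N\mu^2$, and the trace
of $H$ is conserved — both are asserted at $10^{-8}$ relative tolerance in
the tests.

## The default lattice is a calibrated placeholder

The published unit-cell parameters for this dye are in supplementary
material that is not openly redistributable, so the package ships a
*synthetic* herringbone cell and dipole parametrisation
(`default_unit_cell()`, `default_extended_dipole()`), clearly labelled as
such and fully overridable through the YAML config.  It was fixed once, by
two anchors, and not revisited:

* geometry: cell area 1.704 nm² (0.85 nm²/molecule) reproduces the
  observed packing scale of ≈7000 molecules per 100 nm double-walled tube;
  $q = 0.34$ e and $l = 0.70$ nm give $\mu = 0.238$ e nm ≈ 11.4 D, a
  typical cyanine transition dipole mapped on the bridge length;
* excitonics: the lattice constants were scaled once so the ideal
  inner-wall tube ($r = 3.2$ nm, $\theta = 30°$) has a per-site coupling
  sum of −3587 cm⁻¹ and the 2.4%-expanded outer wall ($r = 5.7$ nm)
  −3354 cm⁻¹ — the values reported for the real aggregate's walls — making
  the default system a quantitatively faithful stand-in at the level of
  the quantity that controls the J-band positions.

With this cell, matching the experimental 300 cm⁻¹ inner/outer-wall
splitting requires expanding the outer-wall lattice by ≈3.1% rather than
2.4%: the splitting tracks the *difference* of the coupling sums plus a
band-curvature correction that is lattice-specific.  The package reports
both numbers honestly instead of tuning the cell a second time.

## Disorder models

**Diagonal (energetic) disorder.**  Per-wall Gaussian site-energy shifts,
defaulting to mean +350 cm⁻¹ for both walls with σ = 213 cm⁻¹ (inner) and
231 cm⁻¹ (outer) — the statistics that microelectrostatic calculations on
solvated aggregates deliver.  Sampling is i.i.d. per site and fully
seeded.

**Structural jitter (MD surrogate).**  `structural_jitter()` displaces
positions by isotropic Gaussian noise and rotates dipole axes by
$|N(0, \sigma_{orient})|$ about uniformly random axes (Rodrigues
rotation; unit norms preserved exactly).  Defaults are
$\sigma_{pos} = 0.02$ nm and $\sigma_{orient} = 20°$, calibrated against
the reported *effect* of real packing disorder rather than guessed: in the
real system, solution-phase disorder broadens the per-site coupling-sum
distribution and makes its mean ~7% less negative, which blue-shifts the
J-band.  Positional jitter alone does the opposite — $1/r^3$ is convex, so
distance fluctuations *strengthen* couplings on average and red-shift the
band — hence the surrogate must be orientation-dominated.  At the defaults
the ideal inner-wall mean of −3350 cm⁻¹ (open 500-site tube) weakens to
−3128 cm⁻¹ and the dominant parallel peak moves up by ≈110 cm⁻¹, with the
distribution width growing from ~470 to ~870 cm⁻¹.

What the surrogate does *not* emulate: spatial correlations of the
fluctuations (i.i.d. per site), systematic lattice relaxation, solvent
structure, and any coupling between positional and orientational noise.
Passing tests therefore show that the machinery responds to disorder the
way the real aggregate's spectra do, not that the surrogate is a
substitute for actual trajectory ensembles — those can be ingested with
`read_structure_snapshot()` (PDB/GRO/XYZ plus a two-atom bridge mapping
per residue).

## Spectroscopy

`stick_spectrum()` resolves each eigenstate into parallel ($\mu_{k,z}^2$)
and perpendicular ($\mu_{k,x}^2 + \mu_{k,y}^2$) intensity plus per-wall
weights $\sum_{n \in \mathrm{wall}} c_{kn}^2$.  Homogeneous broadening is
phenomenological: a normalized Lorentzian by default (Gaussian optional),
FWHM configurable and optionally different for the two polarization
channels; there is no attempt to predict homogeneous linewidths
microscopically.  Ensemble spectra are plain averages of per-snapshot
broadened spectra on a common grid.  The wavelength column is a
reindexing $\lambda = 10^7/E$ with no Jacobian applied (plots and files
state the energy axis as primary); displayed spectra are normalized to a
unit maximum only at output time.  Peak metrics use local maxima with
three-point quadratic refinement, FWHM by linear interpolation of the
half-height crossings, and band areas over windows of ±1.5 FWHM around
each peak (overlapping Lorentzian wings bias windowed areas for peaks
closer than ~3 FWHM; the tests use well-separated lines for the ratio
checks).

## Microelectrostatics

The environment-induced shift of a chromophore's excitation energy is
$\Delta\varepsilon = E_e - E_g$: two classical interaction-energy
evaluations against the *same* ground-state environment, one with the
central molecule's excited-state charges and one with its ground-state
charges.  Each evaluation is the central–environment Coulomb energy plus
the induction energy $-\tfrac12 k \sum_i \vec p_i \cdot \vec E^0_i$ of the
environment's polarizable atoms, where the induced dipoles solve
$\vec p_i = \alpha_i \vec E_i$ self-consistently (field of all permanent
charges plus all other induced dipoles; atoms are never polarized by their
own molecule).  The solver is damped Jacobi iteration (damping 0.5,
tolerance $10^{-8}$ e nm on the largest dipole change, 200-iteration cap)
— for two sites it matches the direct $6\times6$ linear solve to
$10^{-10}$.  Both states are treated fully self-consistently; whether a
perturbative treatment of one state would be more appropriate is a
modelling assumption we flag rather than hide.  Pairs of polarizable sites
closer than $(4\alpha_i\alpha_j)^{1/6}$ trigger a polarization-catastrophe
warning; for a two-site system that radius is *exactly* the Jacobi
divergence boundary, so the warning precedes a non-convergence error
rather than a silently wrong number.  Clusters are finite (no periodic
images), carved as whole molecules whose centre of geometry lies within
3 nm of the central molecule's.

Because the quantum-chemically derived charge sets for the real dye are
deposited elsewhere, the package ships synthetic stand-ins
(`synthetic_chromophore()`, `synthetic_water()`,
`synthetic_solvated_cluster()`; also
`inst/extdata/synthetic_chromophore.tsv`): a polymethine-like charge
alternation whose excitation shifts charge along the bridge, SPC-like
water, and a monovalent ion.  They exercise every code path — sign
conventions, induction, solvent-versus-aggregate decomposition via source
tags (shifts are exactly additive over environment subsets when
polarizabilities vanish) — but their absolute shift statistics are not the
real dye's.

## Numerical choices and degenerate inputs

* All lengths nm, energies cm⁻¹, charges e, polarizability volumes nm³;
  angles degrees at interfaces, radians internally; tube axis $+z$,
  azimuth from $+x$.
* Coupling cutoff: none by default (all pairs); a radial cutoff is
  available for large systems.
* Eigenvalues ascend; degenerate subspaces inherit LAPACK's orthonormal
  basis — all reported quantities (intensities, IPR sums over windows) are
  invariant under rotations within a degenerate subspace except the
  per-state IPR itself, which is only summarised window-wise.
* Delocalization uses the inverse participation ratio
  $N_k = 1/\sum_n c_{kn}^4$, summarised as the oscillator-strength-weighted
  mean over a low-energy window (default: up to 300 cm⁻¹ above the
  brightest state); the literature estimator behind the published
  "450 molecules" is not specified in accessible text, so the IPR — the
  standard, monotone, testable choice — is used instead, and reported
  values are bounded by the simulated $N$.
* Degenerate inputs error loudly: parallel lattice vectors, non-symmetric
  or non-finite Hamiltonians, coincident bridge end points, charge-model
  state sets with unequal totals, unbracketed inverse lookups in the
  density scan.
* Every stochastic path takes an explicit seed; ensemble sub-seeds are
  drawn deterministically from the master seed, and sampling restores the
  caller's RNG state.

## Problem sizes

The test suite and the acceptance script run ideal-tube analyses at
500–1000 sites (screw-periodic for band positions), disorder ensembles of
12–20 snapshots at ~500 sites, and microelectrostatics on clusters of a
few dozen molecules — sizes at which every reported quantity is converged
enough for its purpose (band positions to a few cm⁻¹; ensemble statistics
to a few percent) while keeping the whole suite fast.  Full-scale runs
(~7000 sites, hundreds of snapshots) use the same code paths; only wall
time grows.

## Known limitations

Vibronic coupling is ignored (appropriate while the exciton bandwidth
$W \approx 6000$–7000 cm⁻¹ dwarfs $\lambda^2\omega_{vib}$, as here, so
vibronic side-bands are suppressed); no exciton dynamics, transport, or
two-exciton physics; no anisotropic polarizabilities or quantum/classical
embedding in the microelectrostatics; disorder is i.i.d. per site; the
default cell is a calibrated stand-in, not the published structure.
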