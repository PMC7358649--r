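---
title: "Locating membrane-active peptides by neutron reflectometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating membrane-active peptides by neutron reflectometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memreflect)
```

## The problem

Specular neutron reflectometry (NR) measures the reflectivity R of a planar
interface as a function of momentum transfer Q = 4π sin(θ)/λ. The curve
encodes the depth profile of scattering length density (SLD),
ρ = Σᵢ nᵢ bᵢ / Vₘ, through the interface. Because the coherent scattering
lengths of hydrogen (b_H = −3.741 × 10⁻⁵ Å) and deuterium
(b_D = +6.667 × 10⁻⁵ Å) have opposite signs, isotopic substitution — of the
solvent (D₂O vs H₂O), of the lipid acyl chains (d₅₄ labelling), or of
selected peptide residues — changes the contrast without changing the
chemistry. Measuring the same solid-supported bilayer in several solvent
contrasts and co-refining a single structural model is the standard route
to where, and how much of, a membrane-active peptide sits in the bilayer.

`memreflect` implements that chain for anionic PC/PG bilayers on silicon
with the frog-skin antimicrobial peptide maculatin 1.1 as the motivating
system: SLD bookkeeping with deuteration and labile-hydrogen exchange, an
exact slab-model reflectivity kernel, three- and four-layer supported
bilayer models, simultaneous multi-contrast refinement with Monte-Carlo
resampling errors, and the interpretation layer (area per lipid, phase
state, per-leaflet volume fractions, peptide-orientation scenarios).

## Materials and SLD arithmetic

A layer containing lipid, peptide and solvent mixes by volume fraction,

ρ_layer = ρ_lipid Ø_lipid + ρ_peptide Ø_peptide + ρ_solvent Ø_solvent,

with Σ Ø = 1 (`mix_sld()`, enforced during model expansion). Bundled
defaults use literature-typical compositions: PC headgroup C₁₀H₁₈NO₈P at
319 Å³, PG headgroup C₈H₁₂O₁₀P at 289 Å³ with two exchangeable hydroxyl
hydrogens, and C₂₆ di-myristoyl tails (H₅₄ or D₅₄) at 782 Å³; a 3:1 PC:PG
headgroup mix is the default. These are generator/model inputs and are
overridable per material — supplementary tables of the fitted volumes used
by any particular beamtime analysis are not reproduced here.

Labile hydrogens (backbone amides, hydroxyls, amines) are assumed to
equilibrate fully with the solvent: they scatter with
b = (1−f) b_H + f b_D where f is the solvent deuterium fraction. Full
equilibration is an assumption, so f is an explicit parameter of every
contrast. Side chains are kept in neutral protonation states; the
N-terminus contributes one extra labile hydrogen and an amidated
C-terminus contributes an NH₂ (two labile hydrogens).

For the half-deuterated peptide, `maculatin1("d6_nterm")` places methyl
deuterons on the six methyl-bearing residues of the N-terminal half
(L2, V5, L6, A7, V9, A10 of GLFGVLAKVAAHVVPAIAEHF-NH₂); the scheme is an
explicit input because only the *number* and *region* of labelled residues
matter to the SLD contrast. A 21-mer splits into halves as residues 1–10
(N-half) and 11–21 (midpoint residue to the C-half); segment SLDs use the
segment's tabulated-volume share of the molecular volume, so the whole-
peptide SLD is exactly the volume-weighted mean of its halves.

## Reflectivity kernel

`abeles_reflectivity()` is an exact transfer-matrix (Abelès) solution for
a stack of homogeneous slabs, with Névot–Croce Gaussian-roughness damping
of each Fresnel coefficient:

r_{j,j+1} = (k_j − k_{j+1})/(k_j + k_{j+1}) · exp(−2 k_j k_{j+1} σ²),

k_{z,j} = √((Q/2)² − 4π(ρ_j − ρ_ambient)). The principal square root puts
evanescent waves on the positive imaginary branch. Reflectivities are
clipped to ≤ 1 (excursions are at the 10⁻¹⁵ level). The test suite holds
the kernel against an independent Parratt recursion, the closed-form
Fresnel single interface, total external reflection below the critical
edge, Kiessig fringe spacing 2π/d, and the kinematic R·Q⁴ limit.

Instrument resolution is applied as a Gaussian convolution in Q with a
17-point Gauss–Hermite quadrature (nodes by Golub–Welsch); end effects are
handled by evaluating the model at the shifted Q values rather than by
padding. The width is either a constant relative ΔQ/Q (FWHM; default
8.4%, typical of a chopper-defined time-of-flight reflectometer) or a
per-point dQ column read from 4-column data files. The dQ column is
interpreted as a FWHM (ORSO convention) and converted internally by
σ = FWHM / (2√(2 ln 2)). Q is in Å⁻¹ throughout.

## Membrane models

The measurement is made through the silicon block, so stacks run
silicon | oxide | inner heads | tails | outer heads | solvent; "inner"
always means oxide-proximal. `three_layer` treats the tails as one slab;
`four_layer` splits them into inner and outer sub-layers whose
compositions may differ — the configuration that exposes leaflet asymmetry
when the peptide's halves have different SLDs. Structural parameters
(thicknesses, roughnesses, volume fractions) are shared across contrasts;
only solvent SLD and labile-H exchange vary. Design choices where the
field genuinely varies:

* head layers of the two leaflets are tied to a common thickness and
  hydration by default;
* bilayer interfacial roughnesses share one parameter (`rough_bilayer`);
* the oxide is dry by default (`oxide_phi = 0`) and no interstitial water
  layer is inserted between oxide and inner heads (a thin one can be
  emulated by untying the inner-head hydration);
* no hard area-consistency constraint links heads and tails.

## Fitting

`co_refine()` minimises χ² = Σ ((R_model − R)/dR)² summed over every
contrast simultaneously, using a bounded differential-evolution global
search (DE/rand/1/bin; population 15 × n_varied, F = 0.7, CR = 0.9,
relative convergence tolerance 10⁻⁸, capped generations) followed by an
L-BFGS-B polish that can only lower χ². Fits are in linear R weighted by
dR by default; log-R fitting sits behind a flag. Seeds are mandatory
arguments and the RNG state is restored afterwards — there is no hidden
global state, and a fit rerun with its seed is bit-identical.

`monte_carlo_errors()` implements resampling uncertainties: each replicate
perturbs every data point by a Gaussian of width dR and refits from the
best-fit starting point (local polish only by default; a full global
search per replicate is opt-in). The parameter uncertainty is the
2.5th–97.5th percentile interval of the resampled distribution. The
default replicate count is 1008; the test suite uses 100–200 replicates,
which calibration tests show already reproduce the analytic standard error
of a linear model within 15% and ~95% coverage. `linearized_param_cov()`
provides the cheap Gauss–Newton alternative used for error propagation
when full distributions are not needed.

## Decomposition and orientation scenarios

With fitted layer SLDs in ≥ 2 contrasts, `peptide_volume_fraction()`
solves the mixing equation for (Ø_lipid, Ø_peptide, Ø_solvent) with
Σ Ø = 1 by least squares, reporting the design's condition number,
clipping out-of-range solutions to [0, 1] with a flag. Area per lipid
follows A = Vₘ/(τ Ø_lipid) with τ the tail thickness occupied by one
lipid (one leaflet of the tail region). The phase boundary defaults to
47 Å², midway between typical fluid (≥ ~49 Å²) and gel (≤ ~45.4 Å²)
areas for di-C14 PC/PG bilayers — a threshold of 50 Å² would misclassify
fluid bilayers near 49 Å². Ties classify as fluid; the threshold is a
plain argument.

Leaflet SLD asymmetry with a half-labelled peptide admits two readings,
compared by `orientation_scenarios()`:

* **uneven**: whole-peptide SLD in both leaflets, independent per-leaflet
  fractions (4 unknowns over the two leaflets);
* **oriented (N-in / N-out)**: one membrane-spanning population, one
  shared Ø_peptide, the N-half SLD in one leaflet and the C-half SLD in
  the other, solvent still free per leaflet (3 unknowns).

With exactly two contrasts the uneven scenario has as many unknowns as
equations and fits *any* leaflet SLD pair exactly, so a raw residual
ranking can never select an oriented truth. Selection therefore prefers
the most parsimonious scenario whose residual is within a tolerance of
the minimum; the tolerance defaults to the propagated leaflet-SLD
uncertainty (Monte-Carlo draws when available, linearized covariance
otherwise). When the two oriented residuals differ by less than the same
tolerance the orientations are flagged indistinguishable — the physically
common outcome when solvent asymmetry masks the labelling contrast. With
three or more contrasts all scenarios are genuinely over-determined and
the ranking is direct.

## Synthetic data

`generate_study_fixture()` emulates the statistical structure of a
two-contrast supported-bilayer study: 2 tail labellings × (peptide-free,
peptide-bound) × (30 °C fluid, 15 °C gel) × (D₂O, H₂O) = 16 curves, each
carrying its generating model. Truth values are chosen to be realistic
for DMPC/DMPG (3:1) on silicon rather than to reproduce any particular
beamtime: oxide 8.3 Å/3.2 Å roughness (deuterated sample) and
10.7 Å/2.6 Å (hydrogenous); 9 Å heads at 35% hydration; fluid tails 30 Å
total and gel tails 36 Å at Ø_lipid ≈ 0.95, giving areas per lipid of
~55 Å² (fluid) and ~46 Å² (gel); bound-state leaflet fractions
Ø_peptide = 0.17/0.21 (uneven scenario) or a shared 0.18 (oriented
scenarios) with 8% tail solvation. The uneven fractions deliberately use
a modest 0.04 asymmetry: much larger asymmetries become numerically
consistent with an oriented model in a two-contrast design, which would
make the generating scenario unidentifiable in principle, not just in
noise.

Noise is heteroscedastic Gaussian with σ = max(0.05 R, 10⁻⁸) — 5%
fractional counting noise over a background-limited floor — and the same
σ populates the dR column. The Q grid is 120 log-spaced points over
0.012–0.30 Å⁻¹. The generator does *not* simulate time-of-flight
artefacts (chopper wavelength envelope, gravity drop, detector
efficiency), point-to-point correlations from rebinning, or imperfect
background subtraction; passing recovery tests therefore demonstrate the
estimator chain, not robustness to every instrument systematic.

## Numerical choices and problem sizes

* Evanescent k_z: principal square root (positive imaginary part).
* Quadrature: 17 Gauss–Hermite nodes; smearing error is far below the
  simulated noise for ΔQ/Q ≤ 10%.
* Infeasible parameter combinations during a bounded search (layer
  fractions summing past 1) receive a large finite penalty rather than an
  exception, so the population can move off them.
* Decomposition systems with condition number above 10¹⁰ raise an error
  naming the degenerate contrasts.
* Test and example fits use reduced search settings (population 8 ×
  n_varied, ≤ 100 generations) and 100–200 Monte-Carlo replicates; these
  sizes were chosen as the smallest at which the calibration tests are
  stable, and full-size settings are plain arguments.

## Limitations

* Slab models only: no tethered/floating bilayers, air–water monolayers,
  off-specular or polarised scattering, or multiple scattering.
* X-ray SLDs, incoherent scattering and absorption are out of scope.
* The orientation comparison quantifies *consistency* of scenarios with
  the fitted SLDs; with two contrasts it cannot prove orientation, only
  rank parsimonious explanations and flag indistinguishability.
* Tilt angles, pore geometries and oligomeric state are not inferred.
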