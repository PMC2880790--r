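---
title: "Solution characterisation of icosahedral E2/E3BP cores: models and methods"
author: "pdcore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solution characterisation of icosahedral E2/E3BP cores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcore)
```

# The scientific problem

The core of the mammalian pyruvate dehydrogenase complex is a pentagonal
dodecahedral 60-mer built from trimers of the acetyltransferase E2, into
which the E3-binding protein E3BP is integrated. Two stoichiometries have
been proposed: a *substitution* model in which 12 E3BP chains replace 12 E2
chains (48 E2 + 12 E3BP), and an *addition* model in which 12 E3BP chains
sit on the 12 pentagonal faces of an intact 60-mer (60 + 12). The two
architectures differ in total mass (for the truncated core, about
1.67 MDa under substitution) and in whether the pentagonal faces carry
density, so they are distinguishable by solution methods: sedimentation
velocity and equilibrium, small-angle X-ray and neutron scattering, and
bead-model hydrodynamics. Chemical denaturation adds a stability dimension:
E3BP integration destabilises the core.

`pdcore` packages that entire analysis chain as testable code: a synthetic
assembly generator standing in for ab-initio shape reconstruction, the
standard small-angle scattering analyses, bead-model friction computation
with hydration correction, sedimentation-equilibrium mass analysis, and
two-state unfolding fits.

# The synthetic assembly generator

`build_core_model()` places 20 trimer positions on the vertices of a
regular dodecahedron at `inner_radius` from the centre; each trimer is an
equilateral triangle of monomer beads tangent to the circumscribing sphere.
The 12 pentagonal face axes (the vertices of the dual icosahedron) are left
empty except under the addition model, where each carries one extra E3BP
cluster. The centre is hollow by construction. Which 12 vertices host a
heterotrimer under substitution is drawn deterministically from the
assembly seed.

The geometry defaults are *calibration constants*, not measurements:

* `inner_radius = 125` Angstrom, `trimer_edge = 40`, `bead_radius = 20`.
  With these, the core model has a maximum dimension of about 300 Angstrom
  (the truncated-core envelope) and a total bead volume of about
  2.07e6 cubic Angstrom, which equals the anhydrous volume
  `M vbar / N_A` of the truncated core (M = 1,671,348 Da,
  vbar = 0.746 mL/g). Calibrating the bead volume to the anhydrous volume
  makes the model usable directly for friction computation.
* `arm_spec()` defaults (60 arms, 10 beads of radius 5 at 9.5 Angstrom
  spacing, angular diffusion 0.15 rad per step) emulate the disordered
  N-terminal linker/lipoyl arms. They raise the maximum dimension from
  about 300 to about 480 Angstrom, i.e. the arms account for roughly 40%
  of the overall Dmax of the full-length core. Arms are persistent outward
  random walks, self-avoiding only against their own previous bead —
  adequate for disordered arms, not for dense brushes.

What the generator does *not* emulate: real inter-trimer "breathing"
variability, instrument smearing, concentration effects, or any scattering
contrast detail (solvent shell, excluded volume). Passing tests on these
synthetic models therefore validates the analysis chain, not any claim
about real raw data.

# Scattering analyses

`debye_intensity()` evaluates the Debye double sum with uniform-sphere
form-factor amplitudes per bead (point mode available). The q = 0 and
r = 0 limits are analytic, so `I(0)` is exactly the squared total
scattering mass.

`guinier_fit()` iterates the standard low-q window `q Rg <= 1.3` to
self-consistency. One deliberate refinement: by default the regression of
`ln I` on `q^2` carries an extra `q^4` term. On exact Debye curves the
plain two-parameter fit at the 1.3 window overestimates Rg systematically
(about +1.8% for a solid sphere and +2.5% for hollow shells — the
truncation bias of the Guinier approximation, not noise). The curvature
term removes that bias (sphere error < 0.1%) while leaving the noiseless
exponential case exact; `correct_curvature = FALSE` restores the textbook
fit.

`pair_distance_histogram()` supports a point mode (raw centre-to-centre
histogram) and a kernel mode in which the self term of each bead is the
exact uniform-ball self-distance density and each cross pair is smeared
with the 1D convolution of the two beads' chord-projection profiles. The
cross kernel is a far-field approximation (exact as separation grows
relative to bead size); on the fixture models its Rg error is below 1%.
`Dmax` in kernel mode is the largest centre-centre distance plus the two
bead radii. Histograms use left-closed bins; densities are normalized so
that the integral of p(r) equals I(0).

`ift()` inverts `I(q) = integral p(r) sinc(qr) dr` by penalized least
squares on an `n_r`-point grid: second-difference curvature penalty
(weight `lambda_reg`, normalized by the ratio of design-matrix to penalty
norms so the setting is dimensionless), endpoint constraints
p(0) = p(Dmax) = 0, and non-negativity via NNLS. Misfit is the mean
squared (error-weighted) residual and is monotone in `lambda_reg`.

`estimate_dmax()` scans candidate Dmax values and applies a parsimony
rule: the misfit rises by orders of magnitude once Dmax undercuts the
particle and plateaus above it, so the smallest candidate whose misfit is
within a factor (`tol_factor`, default 2) of the plateau minimum is
returned, after a refinement scan brackets the knee at about 1% spacing.
Inside the scan the IFT runs at a finer grid and much weaker smoothing
(`n_r = 120`, `lambda_reg = 1e-6`) than the display defaults, because
locating the knee — particularly the faint tail contributed by flexible
arms — needs the sharpest attainable misfit contrast. A tolerance band of
only a few percent around the best misfit would be meaningless on
noise-free synthetic curves, whose misfit floor is
discretization-dominated and wanders by factors, not percent, along the
plateau; the factor-2 knee band recovers sphere, core and armed-core
dimensions within 2-5%.

`nsd_superpose()` implements the normalized spatial discrepancy: mean
nearest-neighbour squared distances between the two bead sets, symmetrized
and normalized by each set's own mean nearest-neighbour spacing. The
rotation search pre-aligns principal axes (with the four proper flips),
scans a deterministic quasi-uniform rotation grid, then refines by
axis-wise coordinate descent with halving steps. The search runs in both
directions and keeps the better superposition, which also enforces
symmetry of the reported metric. For nearly spherical particles the
principal frame is degenerate, so the grid + descent, not the PCA, does
the real work there.

# Hydrodynamics

`svedberg_params()` is the closed-form bookkeeping from
(M, vbar, s20,w0): friction `f = M (1 - vbar rho) / (N_A s)`, Stokes
radius and diameter, `Dt = kB T / f`, the anhydrous equivalent-sphere
radius `R0 = (3 M vbar / 4 pi N_A)^(1/3)` and the frictional ratio f/f0.
Constants are CODATA 2018 (`N_A = 6.02214076e23`,
`kB = 1.380649e-16 erg/K`) with water at 20 C as rho = 0.99823 g/mL,
eta = 1.002 cP; computation is cgs internally with Angstrom/Svedberg/Da
interfaces. For the truncated core the tabulated inputs give
R0 = 79.1 Angstrom; published tables of these quantities sometimes carry
a dropped decimal here (791), which the test suite annotates rather than
reproduces.

`bead_friction()` offers two routes. The supermatrix method assembles the
3N x 3N Rotne-Prager-Yamakawa pair mobility matrix (Stokes blocks on the
diagonal), solves for bead forces under unit uniform velocity and averages
the total force over the three axes. The plain RPY tensor assumes
non-overlapping spheres, so overlapping models have all radii uniformly
shrunk to the largest admissible scale, with a message; exact touching is
allowed. The Kirkwood route is the orientationally preaveraged double-sum
approximation, valid with overlaps and within a few percent of the
supermatrix on compact assemblies. Rotation-translation coupling is
neglected (no centre-of-resistance treatment), a known bias of at most a
few percent for near-spherical particles. `model_sedimentation()` converts
friction to an anhydrous sedimentation coefficient and applies the
hydration conversion factor `F = (vbar/(vbar + delta1 v1_0))^(1/3)`;
`delta1 = 0.4` g water per g protein is the default hydration, giving
F of about 0.87 in water. Only surface hydration is "seen" by bead-model
friction, which is why this moderate value is appropriate for hollow,
open-faced cores.

`coarse_grain()` is cubic-grid reduction: points collapse to weighted
centroids per cell, per-bead volume proportional to cell mass, then all
radii rescaled so the total bead volume matches the anhydrous target
exactly. Friction of the fixture models changes by under 5% between 7 and
5.7 Angstrom grids.

# Sedimentation equilibrium

`simulate_se()` draws ideal-species profiles
`baseline + sum a_i exp(sigma_i (r^2 - r_ref^2)/2)` with
`sigma = M (1 - vbar rho) omega^2 / (R T)`; at 3000 rpm, 4 C and
M = 1.65 MDa, sigma is about 1.80 cm^-2 over the 6.8-7.25 cm window.
`fit_se()` fits one or two discrete species by Levenberg-Marquardt with
seeds taken from the log slope of the block-averaged radial *derivative*
of the profile — differentiation cancels the unknown optical baseline —
evaluated on the lower third (light-species dominated) and upper third
(heavy-species biased) of the cell, plus a small multi-start grid around
them. Global multi-concentration analysis is represented by fitting each
profile and extrapolating `1/Mapp` linearly to zero concentration
(`extrapolate_Mw0()`), with first-order error propagation. Mass-action
self-association models are out of scope; discrete species suffice for a
predominant core plus a minor irreversible aggregate, and no hard
accept/reject rule is imposed when comparing 1- vs 2-species fits —
residuals are reported and the nested-model inequality is asserted in
tests.

# Two-state unfolding

The linear extrapolation model: `dG(c) = dG0 - m c`, unfolded fraction
`fU = 1/(1 + exp(dG/RT))`, observed signal mixing two linear baselines;
midpoint `Cm = dG0/m` exactly. `fit_two_state()` fits all six parameters
with multi-start over candidate midpoints and steepnesses; flat curves are
rejected as "no transition" when the endpoint plateaus are
indistinguishable against the local noise estimate. `percent_change()`
normalizes to the 0-100% unfolded scale using fitted baselines by default
(endpoint averaging available); out-of-range values are reported, not
clamped. `emission_shift()` reduces fluorescence spectra to peak (with
parabolic refinement) and barycentric mean wavelengths; the barycentre of
a truncated spectral window is deliberately reported as-is, so it shifts
slightly less than the peak when a band sits near the window edge.

A 60-mer dissociating through trimeric intermediates is not a two-state
monomolecular system; the model is adopted as the standard reporting
convention, and the stability parameters of the three constructs
(dG0 = 17.0, 23.6 and 11.0 kJ/mol with midpoints 2.70, 3.19 and 2.88 M
GdmCl for the full-length E2/E3BP, E2-only and truncated cores) are used
as *fixture parameters for recovery tests*, not as quantities re-derivable
from raw data. Their implied m-values (dG0/Cm) differ per construct, and
the package mirrors that without interpretation. R = 8.314 J/mol/K,
T = 298.15 K by default.

# Problem sizes and reproducibility

The test-suite models are a 1-bead sphere, a 42-bead shell, the 60-bead
core and the 660-bead armed core; scattering grids are 120-200 points, IFT
grids 50-160 points, and Monte-Carlo recovery studies use 200 replicates
at 2% (unfolding) or small absolute (equilibrium) noise. These sizes keep
every analysis well-resolved while remaining desk-scale. All randomness
flows through explicit integer seeds (`with_seed` restores the caller's
RNG state); `run_pipeline()` refuses configurations without a seed and its
JSON report (fixed key order, full precision, no timestamps) is
byte-identical across reruns of the same configuration.

# Known limitations

* The Debye scorer has no hydration-shell or excluded-volume contrast
  terms, so model curves are not comparable to absolute-scale experimental
  intensities beyond shape.
* The kernel p(r) cross term is a far-field approximation; for beads in
  contact it slightly narrows the pair kernel (sub-percent Rg effect at
  the fixture geometries).
* Supermatrix friction with overlap shrinkage biases friction low for
  space-filling models; prefer the Kirkwood route or non-overlapping
  models there.
* Dmax of arm-decorated particles is identifiable only through a faint
  p(r) tail; the estimator recovers it within about 5% on noise-free
  curves and degrades with noise.
* Translational friction omits rotation-translation coupling.
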