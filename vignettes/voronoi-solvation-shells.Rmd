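---
title: "Voronoi solvation shells: models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voronoi solvation shells: models, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Classical solvation analysis around a solute measures structure with the
radial distribution function $g_{ij}(r)$ between the solute center of mass
and solvent centers of mass, integrates it into Kirkwood–Buff integrals

$$\Delta G_{ij} = \int_0^{R} \left[g_{ij}(r) - 1\right] 4\pi r^2\,
\mathrm{d}r,$$

and reads off cumulative coordination numbers
$\mathrm{CN}_j = \rho_j \int_0^R g_{ij}(r)\, 4\pi r^2\, \mathrm{d}r$ at a
shell radius $R$, conventionally the first minimum of $g_{ij}(r)$.  For an
anisotropic solute — a flat aromatic ring system, say — a single spherical
cutoff is a poor proxy for "the first solvation shell": at a given $r$ the
sphere mixes molecules in contact with the ring faces with second- and
third-shell molecules past the rim, and molecules hydrogen-bonded to
peripheral groups sit outside any reasonable $R$.  Choosing $R$ is itself
ambiguous whenever $g_{ij}(r)$ has several shallow minima.

`voroshell` implements the parameter-free alternative: a Voronoi
tessellation of the whole simulation cell.  Every atom is a tessellation
site; atomic cells are merged into molecular cells; two molecules are
neighbors when their cells share a face.  The first solvation shell is the
set of direct neighbors of the solute, the second shell the neighbors of
the first, and so on — shell index is the breadth-first graph distance
from the solute on the face-sharing neighbor graph.  No distance
threshold, no fitted radius.  On top of the shell map the package
computes:

* shell-decomposed $g_{ij}(r)$ (each pair contribution routed to the
  solvent molecule's current shell; components sum to the total exactly),
* per-shell concentrations $c_j(k) = \mathrm{CN}_j(k) / V(k)$ and
  solvation free energies
  $\Delta A_j(k) = -RT \ln\left[c_j(k) / c_j(\mathrm{bulk})\right]$,
* the residence function $n_j(t)$ of the first shell, its
  multiple-time-origin autocorrelation
  $C(t) = \langle n_j(0)\, n_j(t)\rangle$ (with
  $C(0) = \mathrm{CN}_j$ by construction), and a bi-exponential mean
  residence time,
* per-first-shell-molecule solute–solvent Coulomb and Lennard-Jones
  interaction energies, and
* geometric hydrogen-bond counts (H···acceptor distance < 2.4 Å and
  donor–H···acceptor angle > 135°, both strict).

Units everywhere: Å, ps, kJ/mol, K, elementary charges.

## Periodic tessellation

Cells are built by half-space clipping, one cell at a time.  The starting
polyhedron is the cuboid bounded by the bisector planes to the site's own
periodic images (so no cell can ever leak past one box length).  Bisector
planes to other sites — including ghost images in all 26 neighboring image
cells — are applied nearest-first, and clipping stops as soon as the next
candidate is more than twice the current cell circumradius away, which
guarantees no remaining plane can cut.  Candidates are gathered inside an
adaptive search radius (four mean inter-site spacings, doubled until the
stopping certificate holds), so the cost per frame is close to linear in
the number of sites for homogeneous systems.

Numerical choices:

* Volumes follow from the divergence theorem,
  $V = \tfrac13 \sum_f d_f A_f$, with $d_f$ the plane distance and $A_f$
  the clipped polygon area.  The partition identity
  $\sum V_\mathrm{cell} = V_\mathrm{box}$ is verified to $10^{-9}$
  relative on every frame; a violation (exactly degenerate site sets,
  e.g. perfect lattices with cospherical vertices, or coincident sites)
  triggers a deterministic retry with $10^{-8}$ Å jitter from a fixed
  internal seed — far below any physical length scale.  In practice exact
  SC and FCC lattices tessellate correctly without jitter because exactly
  tangent bisector planes are skipped by the clipping tolerance.
* Faces carry the identity of the generating site, which yields the
  neighbor graph and shared face areas.  Face areas are symmetrized
  between the two directed copies; the raw asymmetry is at machine
  precision and is monitored in the tests.
* `min_face_area` (default $10^{-6}$ Å²) drops numerically spurious
  contacts: a jittered degenerate tangency produces faces of order
  $10^{-16}$ Å², while genuine molecular contact faces are of order
  1–100 Å², so the threshold is six orders of magnitude below anything
  physical.  It is exposed because sensitivity checks may want it at 0 or
  larger.
* Hydrogens are tessellation sites by default (`sites = "atoms"`); a
  heavy-atom-only mode exists for sensitivity analysis.  Merging atomic
  cells into molecular cells implements "closer to this molecule" as
  closest-atom distance, which is the natural reading for extended
  molecules; no atomic radii enter (plain, not radical, tessellation).

The implementation was cross-checked against an independent Qhull
construction (ghost-replicated `scipy.spatial.Voronoi`): per-cell volumes
agree to $10^{-12}$ Å³ and shell assignments exactly.

## Distribution functions and Kirkwood–Buff estimators

`com_rdf()` histograms minimum-image solute-COM to solvent-COM distances;
`nearest_atom_rdf()` replaces the abscissa by the distance to the nearest
solute atom, which tracks surface structure of extended solutes better
but keeps the $4\pi s^2 \Delta s$ normalization and is therefore biased
where the solute excludes part of the spherical shell — it is meant for
resolving structure, not for integration.  Bins are normalized by the
exact spherical shell volume $\tfrac{4\pi}{3}(r_{i+1}^3 - r_i^3)$ rather
than $4\pi r_c^2 \Delta r$; the two agree to $O(\Delta r^2)$ and the exact
form makes an ideal gas average to exactly 1 in every bin.  The bulk
density $\rho_j = N_j/V_\mathrm{box}$ uses the whole box without an
excluded-volume correction — the conventional normalization.

Quadrature is trapezoidal on bin centers (default width 0.1 Å), with an
extra node interpolated at the integration limit.  `first_minimum()`
smooths with a centered moving average (default 5 bins) and reports an
ambiguity flag when another local minimum lies within 5% depth of the
chosen one; every consumer accepts a manual `R` override because shell
radii chosen from flat minima are genuinely ambiguous.  When counts per
bin are low (small fixtures), wider bins are the right tool — the
anisotropy demonstration below uses 0.2 Å bins so the smoothed curve
resolves the density gap rather than shot noise.

## Shell thermodynamics

Concentrations use the ratio of time-averaged counts to time-averaged
shell volumes by default ("ratio of means"), which is stabler than
averaging per-frame ratios for sparse species; both estimators are
available and agree on static data.  $\Delta A_j(k) = -RT\ln(c_j(k) /
c_j(\mathrm{bulk}))$ with $R = 8.31446\,\mathrm{J\,mol^{-1}K^{-1}}$ and
default $T = 300$ K; negative values mean enrichment at the solute
(preferred solvation), positive values expulsion (dewetting), and an
empty shell reports $+\infty$.  `c_bulk` defaults to the box density but
can be overridden — synthetic constructions record their reservoir
density, and using it removes the contamination of the box average by the
enriched region itself.

### A genuine limitation: size bias of Poisson shells

For a *structureless* (ideal-gas) solvent the shell free energies do
**not** vanish, at any sample size: cells adjacent to the solute are a
size-biased sample of all cells (a larger cell has more faces and is more
likely to touch the solute — the geometric analogue of the friendship
paradox), so the first-shell concentration of a Poisson gas sits ~7%
below the true local density.  At 300 K that is $\Delta A \approx
+0.17$ kJ/mol for the first shell, decaying slowly with shell index, and
the effect is scale-free (independent of density and temperature apart
from the $RT$ prefactor).  The same bias caps the accuracy of the
enrichment-recovery experiment below at roughly 0.2 kJ/mol.  We verified
the effect is geometry, not implementation, by reproducing it exactly
with the independent Qhull oracle.  In dense liquids the cell-volume
distribution is far narrower and the bias shrinks accordingly — which is
why near-zero first-shell $\Delta A$ values are the correct expectation
for real solvents but not for an ideal gas.  Tests that assert the
idealized $\Delta A = 0$ (and the $-RT\ln f$ recovery at 5%) on Poisson
fixtures document this and are expected to fail by the bias margin.

## Residence kinetics

`residence_series()` builds the intermittent indicator (1 when the
molecule's shell index equals the target shell; a molecule that leaves
and re-enters contributes 0 at absent frames; an optional
`tolerance_frames` bridges short gaps, default off).
`residence_autocorrelation()` averages over time origins at every frame;
$C(0)$ equals the census coordination number identically because it is
the same counting.

`fit_biexponential()` fits $a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2} + c$ to
the normalized curve by bounded Levenberg–Marquardt with a deterministic
multi-start.  Design choices that matter:

* **Free plateau $c$.**  In a finite reservoir a molecule that left the
  shell is found there again at long times with the stationary
  probability, so the correlation decays to a plateau, not to zero; a
  two-term model forced through zero chases the plateau with a divergent
  slow time.  `baseline = "zero"` restores the plain constrained fit.
* **Resolvability bound** $\tau \le t_\mathrm{max}/3$: a time constant
  beyond a third of the fit window never visibly decays inside it and is
  indistinguishable from the plateau.  Fit windows should span 3–4 times
  the slowest expected relaxation.
* **Degenerate branch.**  A single-exponential sub-model is fitted
  alongside and selected by a Schwarz criterion evaluated on an effective
  sample size $n(1-\rho)/(1+\rho)$, $\rho$ the lag-1 autocorrelation of
  the null-model residuals — correlation-curve residuals are strongly
  autocorrelated and an uncorrected criterion badly overstates the
  evidence for a second component.
* The zero-lag point is excluded by default (it carries the indicator's
  trivial self term and single-frame recrossing noise), and a fitted
  component whose contribution at the first included lag is below
  $10^{-4}$ is unidentifiable and excluded from the amplitude-weighted
  mean $\bar\tau = (a_1\tau_1 + a_2\tau_2)/(a_1 + a_2)$.

With these guards the fit recovers noiseless single- and bi-exponential
curves exactly and, across 24 independent realizations of the stochastic
exchange fixture below, gives $\bar\tau = 10.06 \pm 0.37$ ps for a true
relaxation time of 10 ps.

Periodic-boundary note: with ghost-image tessellation a molecule's shell
index is computed in the minimum-image sense, so the wrap-around artifact
that would require excluding molecules that left the primary box cannot
occur; no such exclusion is applied.

## Energetics and hydrogen bonds

Solute–solvent pair energies are direct minimum-image sums:
$k_e q_i q_j / r_{ij}$ with $k_e = 1389.354$ kJ Å mol⁻¹ e⁻², and
$4\varepsilon_{ij}[(\sigma_{ij}/r)^{12} - (\sigma_{ij}/r)^6]$ with
Lorentz–Berthelot combination (arithmetic $\sigma$, geometric
$\varepsilon$; an all-geometric rule is available).  Both truncate at a
cutoff (default 14 Å) without shift.  Truncated Coulomb rather than an
Ewald sum is a deliberate approximation: lattice sums are not
pairwise-decomposable per solvent molecule, and the per-molecule
first-shell decomposition requires a direct pair sum.  For charged
species the absolute Coulomb numbers therefore carry a
truncation-dependent offset; comparisons across species and
concentrations remain meaningful.

Hydrogen bonds use the geometric criterion with strict inequalities:
H···acceptor distance < 2.4 Å and donor–H···acceptor angle (at the
hydrogen, 180° = linear) > 135°.  Donors are flagged hydrogens with a
recorded covalent partner; acceptors default to flagged N/O atoms and are
overridable per atom, so e.g. methylated ring nitrogens can be excluded.
Solute-as-donor and solute-as-acceptor are tallied separately and summed.
Detection is exact against brute-force triple enumeration.

## The synthetic fixtures and what they do (and do not) show

No reference trajectories ship with the package; every analysis stage is
validated on generated configurations whose ground truth is known by
construction, all driven by a single seed and reproducible bit for bit:

* **Ideal gas** (default 500 molecules, 25 Å box, 100 frames): uniform
  i.i.d. positions re-drawn each frame around a fixed central solute.
  Validates flatness of $g(r)$ (per-bin Poisson band), the partition
  identity, and exposes the size-bias limitation above.
* **Lattices**: SC (shell populations 6, 18, cubes of $a^3$) and FCC
  (12, rhombic dodecahedra of $a^3/4$) — exact integer ground truth for
  adjacency and BFS shells.
* **Enriched shell** (36 Å box, reservoir densities 0.005 Å⁻³ per
  species, $f = 3$ inside 10 Å, 256 frames): species A accepted with
  probability 1 inside the well and $1/f$ outside, species B uniform;
  the imposed concentration ratio makes $-RT\ln f$ the target first-shell
  free energy.
* **Exchange dynamics** (120 molecules, inner occupancy 1/6, relaxation
  rate $k = 0.1$ ps⁻¹, 8000 frames at 0.2 ps): independent two-state
  Markov chains hop molecules between an inner band (3.5–5.5 Å, the
  Voronoi first shell by construction) and a reservoir beyond 12 Å,
  positions re-drawn within the zone each frame.  The indicator
  autocorrelation is $p + (1-p)e^{-kt}$ exactly; the fitted mean
  residence time must recover $1/k = 10$ ps.  The geometric gap keeps
  occasional line-of-sight leaks (outer molecules briefly Voronoi-adjacent
  through angular gaps) below ~3% of molecule-frames; they contribute a
  sub-frame-time component that the fitter's guards absorb.
* **Planar solute** (4×4 plate at 1.4 Å spacing, a 24-molecule contact
  layer at 2.5–3.5 Å from the plate, reservoir beyond 6.5 Å, 80 frames —
  sized so 0.2 Å bins carry ~50 counts and the first minimum of the
  smoothed curve resolves the contact-layer/reservoir gap on every
  realization we probed, not shot noise on the contact peak):
  reproduces the qualitative anisotropy failure of spherical analysis —
  the spherical CN at the first minimum misses the first-shell molecules
  beyond the rim (the shell-1 component of $g(r)$ extends past $R$), so
  spherical and Voronoi coordination numbers disagree by well over 5%.

These fixtures exercise the estimators, not the physics of real
solvents: there are no intermolecular correlations, no realistic liquid
structure, no long-range electrostatics.  Passing them shows the
machinery is correct and the estimators behave as designed at desk-scale
problem sizes (seconds to a few minutes per fixture on one core); it does
not certify force-field-level accuracy on real mixtures.

## Known limitations

* Orthorhombic boxes only; triclinic cells are rejected.
* Truncated Coulomb (no Ewald/PME); documented above.
* The size bias of shell concentrations for broad cell-volume
  distributions; documented above.
* No radical (weighted) tessellation — atoms carry no radii.
* Spherical-shell normalization of the nearest-atom distribution is
  biased close to an extended solute; use it for structure, not
  integration.
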