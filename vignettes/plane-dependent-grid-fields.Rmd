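---
title: "Plane-dependent 3D grid fields: model, metrics, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plane-dependent 3D grid fields: model, metrics, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridfields3d)
```

## The model

Grid cells in medial entorhinal cortex fire in spatially periodic fields —
hexagonal lattices during planar navigation, vertically elongated columns on
pegboards and helices, and locally-but-not-globally ordered clusters during
volumetric navigation. `gridfields3d` simulates a single account of all of
these regimes: grid computation is *plane-dependent*. Self-motion is
represented relative to a reference plane (the floor, the local tangent plane
of a surface, or an abstract instantaneous plane during free 3D motion), and
the regularity of the resulting fields is limited not by learning but by how
accurately and how often that plane is perceived.

### Motion representation

Six-degree-of-freedom motion with rotational velocity $\omega$ and
translational velocity $v$ is summarized, when $\theta = \lVert\omega\rVert >
0$, by its screw axis: direction $u = \omega/\theta$, pitch
$h = (v\cdot\omega)/\theta^2$, and axis point $q = u \times v / \theta$
(`screw_axis()`). A displacement $\Delta x$ over a short window is split
into a component in the plane normal to $u$ and an elevation along $u$:

$$\Delta x = r\, M^u \gamma + b\, u, \qquad \gamma = (\cos\phi, \sin\phi)^T,$$

where $\hat M^u = 2 z z^T / (z^T z) - I$ with $z = (u + e_z)/2$ is the
180-degree rotation about the bisector of $u$ and the vertical; its first two
columns $M^u$ span the plane (`plane_rotation()`,
`decompose_displacement()`). The pitch and axis point are computed and
carried, but only $(r, \phi, b, u)$ drive the network — the recurrent update
never consumes $h$ or $q$.

Navigation modes gate these components (`navigation_mode()`): intrinsically
planar navigation clamps $\hat M^u \to I$ and drops $b$; projected
(multilayered) navigation drops $b$ but keeps the plane anchoring; volumetric
navigation keeps both; plane-independent navigation bypasses the plane
machinery and integrates $\Delta x$ in the world frame. Pure translation
with self-spin (a rotating body moving along its own axis) has no
established entorhinal signature; we treat it like plane-independent
translation, the same computation as pure 3D translation without a
reference plane.

### Uncertain plane perception

The perceived axis $\xi$ follows a 3D von Mises–Fisher distribution
$P(\xi \mid u, \kappa) \propto \exp(\kappa\, \xi^T u)$, redrawn only when the
step index is a multiple of the refresh interval $\tau$ and held constant in
between (`rvmf()`, `refresh_perception()`). $\kappa$ ("perceptual certainty")
is treated as infinite for accurate perception — a distinct condition, not a
large-$\kappa$ limit. The sampler is exact and rejection-free: the cosine
component has a closed-form inverse CDF, the azimuth is uniform.

A modeling decision that the equations leave open is *where* the erroneous
percept enters. We decompose $(r, \phi, b)$ with respect to the **true** axis
— the animal knows its own egocentric motion — and reconstruct the
allocentric update with the **perceived** axis. The per-step update is then
$B\,\hat M^{\xi} (\hat M^{u})^T \Delta x$: a rotation mapping $u$ to $\xi$.
If instead both steps used $\xi$, the update would collapse to $B\,\Delta x$
for *every* percept and perception error could not affect the fields, which
would contradict the degradation this model exists to study. With accurate
perception the update is exactly $B\,\Delta x$, which is why every metric is
flat in $\tau$ at $\kappa = \infty$.

### The grid network

The four-unit complex activity $a(x)$ is updated multiplicatively,

$$a(x + \Delta x) = \exp\!\big(W^u_r(\phi)\, r + W^u_b\, b\big)\, a(x),
\qquad W^u_r = U\,\mathrm{diag}(i B M^u \gamma)\, U^H,\quad
W^u_b = U\,\mathrm{diag}(i B u)\, U^H,$$

with a fixed unitary $U$ and basis $B = b_0 R_0 \cdot
(\text{tetrahedral rows})$: four unit rows with pairwise dot product $-1/3$
summing to zero, scaled by $b_0 = 10$ and rotated $8^\circ$ about the
vertical ($R_0$) so the lattice is not axis-aligned with the arena
(`grid_constants()`). All generators share the eigenbasis $U$, so they
commute, updates are unitary, and each eigen-coordinate $c_k = (U^H a)_k$
conserves its modulus while accumulating phase $(B\,p)_k$ for effective
displacement $p$. The implementation integrates those phases directly —
mathematically identical to the matrix exponential, $O(4)$ per step and free
of numerical drift; tests cross-check it against a literal complex matrix
exponential. Because phases are additive, path integration over a closed
loop is exact, and the activity is periodic on the lattice dual to the rows
of $B$: an FCC arrangement in 3D, whose horizontal projection (three planar
wavevectors at $120^\circ$; the fourth row is purely vertical) gives a
hexagonal lattice in planar navigation.

Eigen-coordinates start at the unit-modulus phases
$[1, e^{i\pi}, 1, e^{i3\pi/2}]$. Spiking is Poisson with rate
$\lambda = [\lambda_0 + \exp(-c\,(a' - \lambda_1))]^{-1}$,
$\lambda_0 = 1.1$, $c = 15$, $\lambda_1 = 0.7$, where $a'$ is the normalized
real part of a unit's activity; one step is one time unit. The normalization
window is not pinned down by the rate equation alone; we use per-unit
min–max over the whole trial, which makes $a'$ span $[0, 1]$ so that the
logistic's midpoint constraint ($\lambda_1 > 0.5$, the sharp part of the "S"
above the midrange) is meaningful. A constant trace (e.g. the vertical-only
unit under planar navigation) normalizes to 0.5 with a warning.

## Trajectories

`cube_random_walk()` draws each next coordinate uniformly from
$[\max(x - \Delta x_{max}, -1), \min(x + \Delta x_{max}, 1)]$ with
$\Delta x_{max} = 0.08$ per axis; the default trial length is $10^5$ steps,
which covers the $[-1,1]^3$ cube essentially completely at a $0.2$ binning.
`manifold_walk()` runs the 2D walk and sets the altitude from a height
function (bundled: a four-Gaussian-bump surface), attaching analytic unit
normals. For volumetric trials the true reference axis wanders: at every
refresh it is redrawn from vMF centered on the *previous* axis with
$\kappa_{traj} = 200$ (about $5.7^\circ$ per refresh), starting from the
vertical. Centering on the previous axis (rather than a fixed vertical) is
our reading of an "instantaneous plane" — the axis is a slow random walk on
the sphere; a fixed-center variant is available via the `wander` switch.

## Prototype structures and metrics

Reference clouds for FCC, HCP, columnar (COL) and random (RND) field
arrangements are built from lattice vertices inside the cube, rotated
$8^\circ$ like the network basis, each blurred with 500 isotropic Gaussian
points ($\sigma = 0.05$, comfortably separable at the default spacing). The
lattice spacing defaults to $2\pi/b_0 \approx 0.63$, the activity period
along each basis axis, so prototypes live at the model's own scale; COL
stacks hexagonal layers with a *shared* offset at one tenth of the FCC
inter-layer distance. RND uses about 100 uniform vertices, comparable to the
lattice vertex counts.

The metrics suite mirrors standard practice in the 3D grid literature:

* **Rate maps** on a $20^3$ binning of the cube (bin width 0.1, roughly a
  dozen visits per bin on a full-length trial, a workable trade-off between
  occupancy noise and spatial resolution).
* **Spatial information** (Skaggs bits/spike) and **sparsity**
  $\langle\lambda\rangle^2/\langle\lambda^2\rangle$, each standardized
  against 50 circular-shift shuffles of the spike train (uniform offset in
  $[0.05T, 0.95T]$, preserving spike-train autostructure); the Z-score is
  (observed − shuffle mean)/shuffle SD.
* **Field detection** by flat-kernel mean-shift (bandwidth 0.25, binned
  seeding with minimum bin frequency 25, orphans unassigned, clusters under
  30 spikes removed, centers within 0.05 of a cube face removed) and
  **inter-field distances** as nearest-neighbor distances between centers
  (all-pairwise available as an option).
* **3D autocorrelograms**: Pearson-normalized correlation per integer
  offset over overlapping valid bins, masked below 20 overlapping bins.
* **Slice grid scores**: for each slice-normal orientation (azimuth ×
  elevation grid, default $3^\circ$), the central oblique slice is sampled
  on a polar grid (trilinear interpolation, $15^\circ$ angular step), an
  annulus is set from the first trough and first ring peak of the radial
  profile, and rotational correlations give the hexagonal score
  $\min(c_{60}, c_{120}) - \max(c_{30}, c_{90}, c_{150})$ and square score
  $c_{90} - \max(c_{45}, c_{135})$.
* **Structure scores** $\chi_{FCC}, \chi_{HCP}, \chi_{COL}$: calibrated
  once on prototype clouds by locating the local maxima of each structure's
  hexagonal and square score maps; a sample's $\chi$ for a structure is the
  median of its hex scores at that structure's hex maxima plus the median of
  its square scores at the square maxima (`structure_calibration()`,
  `structure_scores()`). The calibration also records each prototype's own
  score as the reference value. The maxima bookkeeping (8-neighborhood
  local maxima on the orientation grid, azimuth wrapping, positive maxima
  only, capped at the twelve highest) is this package's own construction;
  it is validated by the separation properties: every prototype scores
  highest on its own $\chi$, and COL scores far below the FCC/HCP
  references.
* **Modified radial autocorrelation**:
  $\hat A(r) = N(r)^{-1/2} \sum_{\text{shell } (r-1, r]} A_{ijk}$ over
  unit-width Euclidean shells up to half the autocorrelogram edge. The
  shell divisor matters: dividing by $N(r)$ itself would renormalize each
  shell to a plain mean, which shrinks quadratically with radius and washes
  out widely spaced repeats, so the sub-linear $\sqrt{N(r)}$ is used.

## The mode-switching arena

`run_switch_experiment()` walks an agent over a square arena that is flat
for $x<0$ and tilted for $x\ge 0$ (default tilt $30^\circ$; the tilt and
the per-region scales $b_0 = 10$ vs $12.5$ are free choices of this
demonstration, all configurable — the phenomenon is qualitative, requiring
only that the two regions differ). Visits follow
Flat → Slope → Flat → Slope with durations drawn from [5000, 7000] steps;
between visits the agent walks to the border so the path stays continuous.
Because the two regions integrate with different scales and planes, phases
accumulated in one region shift the grid of the other: on re-entry the
fields reappear *translated* by a common vector (visible as an off-center
peak in the repeat-visit map cross-correlation,
`switch_map_correlation()`). The "virtual walk" restoration
(`virtual_walk()`) resets the eigen-coordinates to the stored exit state and
replays the exit-to-entry displacement in 100 equal sub-updates; since
updates commute, the result is independent of the number of sub-updates
(asserted to $10^{-9}$ in the tests), and restored second-visit fields
overlap the first visit to within a field radius.

## What the simulations do and do not show

The generator emulates the study's own conditions: a bounded uniform
random walk, ideal Poisson spiking from a noiseless network, and a single
well-defined perception process. It does not emulate realistic rodent or
bat kinematics (speed and head-direction statistics), sensor-specific error
structure, conjunctive or modular grid populations, or any plasticity.
Passing tests therefore validate the model's internal logic and the metric
implementations — not claims about biological recordings.

Problem sizes in the test-suite and acceptance runs are scaled-down
versions of the full campaign (e.g. 2–8 trajectories of $2\times 10^4$
steps instead of 8 of $10^5$; $\kappa \in \{300, \infty\}$ and three to
eleven $\tau$ values instead of the full grid). These sizes were chosen so
the qualitative contrasts of interest — Z-scores far above 2.58, the
$\tau$-degradation under uncertainty, $\tau$-independence under accurate
perception, prototype separation — are all resolved with comfortable
margins at desktop runtimes.

## Numerical choices and degenerate inputs

* $\hat M^u$ is undefined for $u$ antiparallel to the vertical; strict mode
  raises an error, simulation mode perturbs the axis by $10^{-6}$ rad
  toward $+e_x$ (the trajectory process never produces the exact
  antiparallel axis, and silent NaNs must be impossible).
* $\phi$ uses the atan2 convention on $(-\pi, \pi]$; a vanishing planar
  component ($r < 10^{-12}$) sets $\phi = 0$.
* Slices of the autocorrelogram with no detectable ring (no radial trough
  followed by a peak) are masked rather than scored; empty MRA shells
  report 0 with a zero count.
* Shuffle Z-scores error on a degenerate (zero-SD) null rather than
  returning infinities.
* The first step of a trial counts as a perception refresh; a trial whose
  $\tau$ exceeds its length therefore has exactly one percept throughout.

## Reproducing the numbers

`scripts/acceptance.R` (repository root) regenerates every reported
quantity from scratch at the scaled-down sizes above, seeding all
randomness from a single master seed via per-stage substreams. The
package-level test suite (`testthat`) carries the exact algebraic
invariants (unitarity, involution, loop closure, closed-form information
measures), the sampling oracles (vMF moments, Poisson moments), and the
end-to-end scientific checks described here.
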