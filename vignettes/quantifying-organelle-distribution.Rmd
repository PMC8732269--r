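---
title: "Quantifying radial organelle distribution in single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying radial organelle distribution in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellsweep)
```

## The problem

Organelles such as the endoplasmic reticulum redistribute between the
perinuclear region and the cell periphery, and can collapse asymmetrically
to one side of the nucleus. Judging such changes by eye does not scale and
is not quantitative. `cellsweep` turns a 2D single-cell fluorescence image
(typically a summed-intensity projection of a confocal z-stack) plus
nucleus/cell masks into two per-cell numbers:

* **MDR (mean distribution radius)** — the fluorescence-weighted mean
  radial position of the signal. Higher MDR means more peripheral
  ("dispersed") signal.
* **Asymmetry** — how strongly the signal concentrates at one side of the
  nucleus, in $[0, 1]$.

## The model

The image is treated as a discrete spatial distribution. Starting from the
nucleus centre $c$, a ray is swept through $360^\circ$ (0.1$^\circ$ steps
by default), taking a bilinear line profile at each angle. This produces
an $(r, \theta)$ representation $F(\theta_i, r_j)$ of the cell's
fluorescence. Because the polar sampling lattice does not match the square
pixel lattice, each sample carries a Jacobian area weight
$w_{ij} = r_j \, \Delta\theta \, \Delta r$, so that weighted polar sums
estimate Cartesian integrals; where true values are integrals over space
they are estimated at pixel resolution by a sum over the samples.

Cells differ in size and outline, so the radial axis is normalized per
angle. With $r_{ne}(\theta)$ the nuclear-envelope radius and
$r_{edge}(\theta)$ the cell-edge radius along the ray at $\theta$:

$$u = \begin{cases}
100 \cdot \dfrac{r - r_{ne}}{r_{edge} - r_{ne}} & r \ge r_{ne}
\quad \text{(cytoplasm, } 0..100\%)\\[1ex]
25 \cdot \left(\dfrac{r}{r_{ne}} - 1\right) & r < r_{ne}
\quad \text{(nucleoplasm, } -25..0)
\end{cases}$$

The nucleoplasm band acts as a control region; note that in a 2D
projection it also contains cytoplasm and nuclear envelope lying above and
below the nucleus, and no correction is applied for that. The mapping of
the nucleoplasm is linear in $r$ — the minimal assumption for a band that
is only required to stretch over $[-25, 0]$.

The area-weighted intensities are then normalized into a **spatial
probability mass function** $p_{ik} \ge 0$, $\sum p_{ik} = 1$, over
(angle, $u$) samples, and the two statistics are

$$\mathrm{MDR} = \sum_{i,k} p_{ik} \, \rho_{ik}, \qquad
\mathrm{asymmetry} = \Big|\sum_i q(\theta_i)\, e^{\mathrm{i}\theta_i}\Big|,
\quad q(\theta_i) = \sum_k p_{ik},$$

with $\rho$ either $u$ (normalized scale, %) or the raw radius in
micrometres. Both MDR scales are reported; group comparisons default to
the normalized scale so cells of different sizes are commensurable.

**Why this asymmetry definition.** The angular marginal $q$ is a
distribution on the circle, and its mean resultant length is the canonical
normalized measure of concentration toward one direction: it is bounded in
$[0,1]$, exactly 0 for angularly even signal, exactly 1 for signal at a
single angle, and invariant under rotation of the frame. The accompanying
`mean_angle` is rotation-equivariant and points at the signal's centroid
direction.

## Assumptions

* The cell outline is **star-convex about the nucleus centre**: every ray
  crosses the nuclear envelope and the cell edge exactly once. Boundary
  tracing uses the *last* mask crossing along each ray (robust to holes in
  masks); rays that never cross raise a degenerate-geometry error rather
  than silently truncating.
* Masks (nucleus, cell, neighbour exclusion) are inputs; segmentation is
  upstream of this package. The nucleus centre defaults to the
  nucleus-mask centroid, with a manual override for non-convex nuclei.
* Signal from neighbouring cells is removed by zeroing the exclusion mask.
  Zeroing keeps the PMF definition simple; if the exclusion region
  overlaps the analysed cell, peripheral mass is slightly deflated.
* No background subtraction is applied by default.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `theta_step` | 0.1 | degrees | angular resolution of the sweep (3600 profiles) |
| `radial_step` | 0.5 | pixels | sampling along each ray (~2x pixel oversampling) |
| `u_step` | 0.5 | % | normalized radial grid (250 bins over $-25..100$) |
| `domain` | `full` | — | PMF support; `cytoplasm_only` drops $u<0$ |
| `smooth_deg` | 0 | degrees | optional circular smoothing of boundary radii |
| `center_override` | none | px | manual nucleus centre |

The default PMF domain is `full` because the nucleoplasm band is a control
region, not an excluded one; every reported metric records which domain it
used. Halving `theta_step` and `radial_step` moves MDR by well under 0.5%
on smooth phantoms (checked in the test suite), so the defaults are
comfortably inside the converged regime; `theta_step = 0.5` is used in
several analysis scripts where sub-percent angular resolution is not at
stake, at a ~7x runtime saving.

## The synthetic-cell generator and its oracle

Real images of this kind are hand-curated single cells, which makes a
ground-truth benchmark impossible from real data alone. The generator
builds phantoms with *analytically known* distributions:

* **Geometry**: an elliptical nucleus inside a star-convex outline
  $r_{cell}(\theta) = R_0 (1 + \sum_k a_k \cos(k\theta + \varphi_k))$ with
  $\sum_k |a_k| < 0.5$, on a 256 px image at 0.1 um/px; cell radii around
  80–100 px and nucleus semiaxes around 20–34 px, jittered per cell.
* **Field**: the density factorizes into a von Mises angular part
  (concentration $\kappa$; $\kappa = 0$ is angularly even) and a radial
  mixture *specified in the normalized coordinate $u$* — perinuclear
  Gaussian, peripheral Gaussian, uniform on $[0,100]$ — so the
  normalized-scale ground truth is independent of cell shape.
* **Detection**: expected photons are normalized to a photon budget
  (default $10^6$, a bright stable marker in a summed projection), plus
  constant background (0.5 counts/px) with Poisson shot noise and Gaussian
  read noise (sd 2), each switchable for analytic tests.

Ground truth comes from an independent quadrature oracle: midpoint
integration of the continuous density on a 3600 x 2000 (angle, $u$) node
grid, refined once to check convergence to $10^{-4}$. The oracle never
touches the image-space code path, so pipeline-vs-oracle agreement is a
genuine two-route check. For angular bias the oracle reproduces the von
Mises mean resultant length $I_1(\kappa)/I_0(\kappa)$ to six decimals.

Three presets reproduce the *direction* of the biological phenotypes:
`wildtype` (perinuclear-weighted, even), `dispersed` (peripheral-weighted,
higher MDR) and `clustered` (wildtype radial profile with $\kappa \approx
3$, higher asymmetry). No parametric form for the real intensity profiles
exists, so the presets are calibrated to ordering, not magnitudes.

What the phantoms do **not** emulate: ER tubule/sheet texture,
out-of-focus haze, uneven illumination, segmentation errors, or 3D
structure. Passing tests therefore demonstrate correctness of the
*measurement* given masks and a 2D image, not robustness to upstream
imaging artefacts.

## Numerical choices

* **Square-pixel correction** = bilinear subpixel interpolation along rays
  plus the Jacobian weights above; this is the standard resolution of the
  polar/Cartesian mismatch and is validated by the conservation invariant
  (Cartesian total vs weighted polar total vs weighted normalized total,
  pairwise within 2% on smooth phantoms).
* **Boundary localization**: masks are interpolated bilinearly and
  thresholded at 0.5, with the crossing refined linearly — subpixel
  accuracy (within 1 px of analytic radii for circles and rotated
  ellipses).
* **Radial resampling** onto the fixed $u$ grid deposits each sample's
  mass and area onto the two adjacent bins (conservative cloud-in-cell
  splitting); intensities are mass/area, so a constant image stays exactly
  constant on the $u$ grid.
* **$r_{max}$** is the furthest cell-mask pixel plus a 2 px margin, so the
  sweep always reaches past the cell.
* **Degenerate inputs** (empty nucleus, zero signal, $r_{ne} \ge
  r_{edge}$, rays without crossings) raise stage-named errors; metrics are
  never silently `NaN`.
* In phantom rendering the $1/r$ Jacobian factor is floored at $r = 1$ px
  to regularize the centre pixel; the presets place negligible mass there.
* **Seeds**: a panel's master seed derives per-cell substreams as `seed +
  cell_index`, so any cell of any panel is reproducible in isolation.

## Problem sizes in the shipped analyses

The analysis scripts and acceptance checks use 20 cells per phenotype
panel on 256 px images — comparable to the `n = 30` cells per condition
typical of this kind of experiment — and validate oracle agreement on
10–20 random phantoms at default grid settings. The type-I-error
calibration of the statistics pathway uses 500 two-group null panels of
30 cells each, drawing per-cell metrics from the ground-truth oracle
rather than rendering 30,000 images: under the null the group structure
lives entirely in the per-cell metric values, so this exercises exactly
the test pathway while keeping the simulation honest and fast.

## Known limitations

* 2D only; the projection folds the space above and below the nucleus
  into the nucleoplasm band (see above).
* Asymmetry is the *first* circular moment: a perfectly bimodal
  (antipodal) concentration scores near 0. That is the intended meaning —
  "one-sidedness" — not general angular non-uniformity.
* Cells whose exclusion mask overlaps the analysed cytoplasm lose that
  mass (documented deflation), and heavy uniform background biases MDR
  toward the value of a uniform-area distribution; background subtraction
  is deliberately out of scope.
* `mdr_raw` depends on cell size; use the normalized scale to compare
  groups of differently sized cells.
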