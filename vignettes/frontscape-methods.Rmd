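---
title: "Fronts in heterogeneous landscapes: models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fronts in heterogeneous landscapes: models and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(frontscape)
```

## The problem

A population expanding into empty habitat — microbes on a plate, an
invasive plant across a landscape, a phage plaque on a bacterial lawn —
advances as a front driven by local growth and dispersal. Real habitats are
rarely uniform: finite patches may be impossible to invade (*obstacles*,
local front speed 0) or easier to invade than the background (*hotspots*,
local speed $v_2 > v_1$). `frontscape` provides three complementary
descriptions of how randomly placed finite-sized patches shape front speed
and front shape in two dimensions, plus the ensemble experiments that
quantify their collective effect.

1. **Individual-based model (IBM).** A birth–coagulation–diffusion process:
   each individual duplicates in place at rate $\mu$; it dies at rate
   $\lambda n$ when $n$ *other* individuals share its $\delta \times
   \delta$ interaction cell; it diffuses with coefficient $D$. Defaults
   $\mu = \lambda = \delta = D = 1$. Features act through a locally modified
   diffusivity $D_2$ (0: impermeable obstacle; $>D$: hotspot) or a modified
   birth rate.
2. **Least-time (Eikonal) description.** When the front width is small
   against the feature scale, the front is an interface moving normal to
   itself at a purely local speed $v(\mathbf{x})$, and the first-arrival
   time obeys $|\nabla T(\mathbf{x})| = 1/v(\mathbf{x})$. We solve this
   with a first-order upwind fast-marching method on a rasterized
   landscape. Closed forms exist for single features: the geodesic
   (tangent–arc–tangent) front around a disc obstacle, the healing kink
   ($\theta \approx \pi - 2w/d$, indent $s \approx w^2/2d$ behind an
   obstacle of half-width $w$ after travel $d$), and the hotspot bulge, a
   radial wave of radius $r = d + k$ with permanent advance
   $k = 2l(1 - v_1/v_2)$ for a hotspot of half-length $l$.
3. **Event-based scattering.** Fronts in rhombus-obstacle landscapes are
   exactly the envelope of radial waves scattered from obstacle corners;
   hotspot landscapes are approximated by a cascade of activation events in
   which every touched hotspot emits a radial wave from its centre.

## Geometry and conventions

The habitat is a channel of length `Lx` (propagation along $x$) and width
`Ly`, periodic transversally by default. Landscapes are Poisson: the number
of features is drawn with mean $\rho L_x L_y$ and centres are uniform;
overlaps are allowed, which gives the covered area fraction
$\phi = 1 - e^{-\rho \pi R_a R_b}$ for ellipses. Grids are cell-centred
with lattice constant $h = 1/15$ of the unit feature scale by default, the
resolution at which a unit disc is covered by roughly 700 cells. Cell
centres decide feature membership (no anti-aliasing): the first-order
solver error dominates any sub-cell refinement of the mask.

The channel blocks only when overlapping obstacles form a cluster that
wraps the periodic transverse direction; this is detected exactly in the
continuum by union-find over pairwise overlaps (equal axis-aligned ellipses
and rhombi reduce to unit discs and unit $L_1$ balls after scaling the
axes). The same union-find machinery, in a square box with virtual top and
bottom nodes, estimates the percolation threshold of overlapping discs by
bisecting the area fraction until the spanning probability crosses $1/2$;
at box side $60R$ and 400 trials per point this reproduces
$\phi_c \approx 0.68$.

## Stochastic simulator: updating scheme and what it equilibrates to

The IBM uses fixed-time-step binomial updating (default $dt = 0.1$), in the
order birth → death → diffusion; any other order differs at $O(dt^2)$.
Deaths bin the full cohort (parents plus newborns) into a lattice of
$\delta$-cells anchored at the origin. Moves ending inside a $D_2 = 0$
feature are rejected, which keeps obstacles impermeable without a boundary
layer; $y$ wraps, $x$ reflects.

Two properties of this scheme deserve emphasis because they differ from the
deterministic intuition:

* The mean-field carrying capacity is $(1 + \mu/\lambda)/\delta^2 = 2$ for
  the defaults, but the *stochastic* model equilibrates far below it
  (measured $\approx 0.67/\delta^2$ at $dt = 0.1$). Two effects combine:
  newborns appear in their parent's cell, so same-cell pairs are strongly
  over-represented relative to a Poisson configuration, inflating the
  coagulation rate; and at $dt = 0.1$ the per-step death probability
  $\lambda n_{\text{others}} dt$ is not small, adding an $O(dt)$ bias
  (halving $dt$ raises the density towards $\approx 0.95$). Front speeds,
  the quantities this package reports, are insensitive to this offset —
  the measured speed ratio between $D_2 = 2.5 D$ and $D$ systems is 1.80.
* Front speeds sit well below the continuum FKPP value $2\sqrt{D\mu}$
  (the demographic-noise cutoff at a handful of individuals per cell), and
  the speed ratio between two diffusivities is *not* $\sqrt{D_2/D_1}$:
  a larger $D$ widens the front, weakens the cutoff, and pushes the ratio
  above the square root (measured 1.80 for $D_2/D_1 = 2.5$, 1.62 for
  $D_2/D_1 = 2$).

The front of a population snapshot is extracted per transverse
$\delta$-row as the rightmost occupied cell of the connected bulk;
occupied cells more than $5\delta$ ahead of the row's 95th-percentile
occupied cell are discarded as stray diffusers. There is no canonical recipe for this step; this one is the package's
own, and the
extracted speed is insensitive to the filter width and to the recording
interval within one standard error.

## Eikonal solver

First-order Godunov fast marching with a binary heap; the transverse
periodic wrap is built into the neighbour stencil. Obstacle cells
($v = 0$) are never accepted and keep $T = \infty$, as do enclosed
pockets. A planar source initialises the first column at $T = h/(2v)$ so
that the homogeneous solution $T = x$ is exact along the axis; point
sources seed an exact-distance disc of radius $3h$.

Mean front position at time $t$ is the row-average of the rightmost
sub-cell-interpolated position with $T \le t$ ("fill-in" convention:
overhangs and lagging fjords behind obstacles do not pull the front
back). Relative speed $\nu$ is the least-squares slope of that position
over the trailing half of the usable time range, after discarding a 20%
transient, divided by $v_1$; a blocked channel reports $\nu = 0$ with a
flag.

Known error behaviour of the first-order scheme, measured in the test
suite: point-source distances are accurate to 2% beyond three feature
radii; in the shadow of a disc obstacle the error against the closed-form
geodesic is concentrated in a boundary layer behind the tangent points and
decays only like $h^{0.6}$ (a generic property of first-order upwind
schemes at diffraction points), so max-norm agreement tightens in absolute
terms but *not* in units of $h$. Speeds on random landscapes are
well-converged at $h = 1/15$ (halving $h$ moves $\nu$ by under 0.5%).
Where a result is sensitive to the residual $O(h)$ bias — the weak-hotspot
scaling excess below — `scaling_exponent()` Richardson-extrapolates from
$h$ and $h/2$ on identical landscapes.

## Event-based construction

For rhombi, corner activation times come from Dijkstra on the visibility
graph (corners plus periodic images plus the planar source; an edge exists
when the connecting segment misses every obstacle interior, checked by
slab-clipping in scaled coordinates where each rhombus is a unit square).
The front is then the per-row maximum of the clipped planar front and all
visible corner waves. This construction is exact for rhombi and the tests
hold it to the Eikonal solution within 2%.

For hotspots the cascade activates each circle at the earliest time any
existing wavefront touches it, and the new wave follows
$r(t) = v_1 (t - t_0) + R(1 - 2v_1/v_2)$, the unique linear radius law
that reproduces the single-hotspot bulge $r = d + k$ exactly. Two rules are genuine design choices:

* *Touch-to-touch increments.* For centre distance $d \ge 2R$ the
  increment is $2R/v_2 + (d - 2R)/v_1$ (cross the activating hotspot at
  $v_2$, the gap at $v_1$); for overlapping pairs ($d < 2R$) the
  centre-to-centre segment lies inside the union and is charged $d/v_2$.
  Using the radius-law formula for overlapping pairs instead activates too
  early and makes the event speed *exceed* the Eikonal speed, violating
  the construction's defining property of being a lower bound.
* *No intervening acceleration:* waves travel between features at $v_1$
  even when crossing other hotspots. This keeps the construction an
  underestimate; the price is a deviation from the Eikonal reference of
  3.5–4.5% at $\phi = 0.3$, $\gamma = 4$ (slightly above the ~3% agreement quoted for
  this regime), closing in the dilute and the
  nearly-covered limits.

## Ensemble experiments

`speed_vs_area_fraction()` scans $\phi$ for any template (desk-scale
default: channel $50 \times 300$, 5 seeds per point; the full-scale
$50 \times 1300$ channel is one argument away). Blocked obstacle
landscapes are flagged and excluded from fits. The reproduced orderings:
circular obstacles of different radii collapse at equal $\phi$ (similarity),
ellipses with the long axis along the front slow the front more, and the
thin-rod Monte-Carlo chain estimator (consecutive overlapping rods,
path-length inflation $\sqrt{x^2 + y^2}/x$ per pair with exponential
spacings and uniform overlaps) bounds the rod system from below.

`scaling_exponent()` fits the weak-hotspot excess
$\nu - \nu_m \propto (\gamma - 1)^{4/3}$ at $\phi = 0.5$, where
$\nu_m = \phi\gamma + 1 - \phi$ is the spatial mean and
$\nu_h = (\phi/\gamma + 1 - \phi)^{-1}$ the harmonic-mean lower bound.
With the prescribed grid $\gamma \in \{1.05, 1.1, 1.2, 1.4\}$ the fitted
slope is $1.16 \pm 0.02$, robust to Richardson extrapolation and to the
full-scale channel; the local slope rises towards $4/3$ as
$\gamma \to 1$ (1.24 for the 1.05–1.1 pair against 1.10 for 1.2–1.4),
consistent with an asymptotic weak-disorder law approached slowly from
below. The package reports the honest fit rather than forcing the
asymptote.

`refraction_experiment()` measures effective speeds on homogeneous
hotspot landscapes at two densities and compares the front tilt across a
45° interface with Snell's law,
$\Delta y/\Delta x = \tan(\pi/4 + \arcsin(v_r / \sqrt{2} v_l))$. Two
measurement choices matter. The composite channel is closed (not
periodic): a 45° interface is incompatible with a periodic seam, and wall
effects are part of the experiment. And the tilt cannot be read from a
late-time front snapshot — in a closed channel, waves seeded at the walls
progressively erode the tilt back towards vertical — so it is read from a
plane fit of the *arrival-time field* in a band $5R$–$40R$ downstream of
the interface (interior 60% of rows), which records the refracted
orientation before erosion. Agreement is assessed on the tilt angle;
the slope $\tan$ of a near-vertical front amplifies small angular noise.

On the absolute speeds: with unit-radius hotspots at $\gamma = 2$, the
dense-side density $\rho = 0.150$ corresponds to $\phi = 0.376$ and a
converged relative speed of 1.59, while the reference value for the
dense side, 1.74, coincides with the speed this package measures at
$\phi = 0.50$. The dilute side ($\rho = 0.015$) reproduces its reference
value 1.14 exactly. The radius of the hotspots behind the dense-side
reference is not documented; this package keeps the stated assumption
$R = 1$ and reports what that world gives.

## Synthetic data, and what a green test establishes

Everything here is synthetic by construction: landscapes are Poisson discs
/ ellipses / rhombi of a single template, and the IBM is the generative
model itself. The generator reproduces the stated channel geometries,
densities, lattice constant and seed conventions; it does not emulate
correlated or fractal landscapes, mixed feature shapes or sizes,
curvature-dependent front speeds, or demographic fluctuations in the
Eikonal layer (which is deterministic by design). A green ensemble test
therefore establishes correctness of the algorithms on the stated world,
not robustness to landscape classes the generator cannot produce.

## Degenerate inputs and tie-breaks

Zero density gives empty landscapes, uniform fields and $\nu = 1$ exactly.
Features may protrude past the $x$ boundaries (clipped by the grid).
Segment–rhombus grazing contacts (a visibility segment touching a corner
or running along an edge) count as unobstructed, with tolerance $10^{-9}$
in scaled coordinates. Waves with non-positive radius contribute nothing
to envelopes. The fast-marching heap breaks ties by insertion order; the
solution is independent of tie order (re-solves are bit-identical because
the update is a deterministic function of accepted-neighbour values).
Population extinction terminates an IBM run with a flag; empty transverse
rows are excluded from front averages.
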