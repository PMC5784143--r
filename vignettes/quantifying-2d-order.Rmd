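---
title: "Quantifying translational, entropic and angular order in planar dispersions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying translational, entropic and angular order in planar dispersions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PlanarOrder)
```

Self-assembled monolayers — block-copolymer micelles, colloids, quantum
dots, cells on a substrate — are usually *well but not perfectly* ordered.
Deciding whether two visually similar micrographs differ in their degree
of order, and in *which kind* of order, needs quantitative metrics rather
than visual judgement. PlanarOrder works from the only thing all such
images share: the 2D centroid coordinates of the objects, in a bounded
rectangular observation window. It quantifies three distinct kinds of
local order:

* **translational** — do inter-particle distances repeat at lattice
  translations? (pair correlation function, lattice disorder parameter);
* **entropic** — how is free area partitioned among particles?
  (window-clipped Voronoi tessellation: coordination numbers,
  disclination defects, valence maps);
* **angular** — are a particle's bonds arranged with a definite arc
  symmetry? (Minkowski bond orientational order parameters
  $q_\ell$).

This vignette explains the models behind each metric, the parameters that
matter, the numerical choices made, and what the synthetic generators do
and do not emulate.

## The data model

A `PointPattern` is an ordered set of $N \ge 1$ centroids inside an
`ObsWindow` $[x_{min},x_{max}]\times[y_{min},y_{max}]$, with one shared
length unit. The intensity is $\lambda = N/A_{box}$. Unit handling is
deliberately rigid: any pixel-to-physical conversion (e.g. 2.44 nm/px for
a typical AFM scan) is applied exactly once, at ingestion by
`readPattern()`, and recorded; everything downstream is unit-agnostic.
Image-convention input (y down) is flipped at read time, because the
valence maps reference a "+y" orientation. When no window is supplied the
tight bounding box is used; an explicit window always wins, since
$\lambda$ — and everything derived from it — depends on the window the
counts were observed in.

## Voronoi tessellation and the entropic metrics

`tessellate()` partitions the window into one convex cell per particle.
Cell polygons are computed by clipping the window rectangle against the
perpendicular-bisector half-planes of each particle's Delaunay neighbours
(the neighbour graph comes from deldir; the polygons are recomputed here
in full double precision). This construction makes the area identity
$\sum_i A_{vor}^i = A_{box}$ hold to relative $10^{-9}$ — it is enforced
by the class validity method, and is the invariant everything else leans
on.

Facets shorter than `facetEpsilon` ($10^{-6}\times$ the window diagonal
by default) are degenerate point contacts and are dropped symmetrically.
The exact square lattice is the canonical case: its four-cell vertices
produce zero-length diagonal facets, so filtering yields the intuitive
coordination 4 deterministically; any jitter beyond the tolerance
resolves each vertex along one diagonal, giving $4 + \mathrm{Bin}(4,
\tfrac12)$ facets per interior cell — coordination 6 in the mean, as the
Euler relation requires.

Cells touching the window boundary are flagged `isEdge`: their true cells
extend beyond the image, so including them biases local densities low.
All local statistics exclude them by default. The area-based disorder
statistics go one step further and use *buffered* interior cells
(`interiorCells()`): cells Voronoi-adjacent to an edge cell are excluded
too, because a window that crops a lattice close to a row boundary can
leave outermost cells whose polygon stops just short of the window —
geometrically interior, but with truncated neighbourhoods and inflated
areas. Without the buffer these leak a spurious floor into the disorder
parameter at small jitter. Coordination histograms keep the plain
edge-cell exclusion (both modes are exposed via `excludeEdge`), since the
choice for histograms is a matter of convention rather than bias.

### The local spacing and the lattice disorder parameter

A hexagonal cell of area $A$ has apothem
$r_{hex} = \sqrt{A}\,(2\sqrt3)^{-1/2}$; twice that is the spacing of the
hexagonal lattice with the same local density. Averaged over interior
cells this gives the mean expected spacing
$\langle 2 r_{hex}^{vor}\rangle$ — an estimate of the inter-object
spacing that needs no distance measurements and is insensitive to edge
artifacts. The spread of the local $r_{hex}$ values is the lattice
disorder parameter, reported in two forms: the direct form
$\Delta r = \sqrt{\mathrm{Var}(r_{hex})}$ (the canonical value), and the
first-order error propagation
$\Delta r = |\partial r_{hex}/\partial A|\,\Delta u_r$ with
$\Delta u_r$ the standard deviation of interior areas and the derivative
evaluated at the mean interior area (the evaluation point is a choice;
the mean is the natural expansion point of the propagation formula). The
two agree to first order in the disorder and are tested to agree within
20% in that regime; both vanish identically on a perfect lattice. The
estimator responds to *relative* neighbour displacements, so it recovers
the generator's jitter scale up to a fixed factor ($\approx 0.2$,
measured once against the generator and then held fixed as a regression
reference); what carries scientific meaning is its strict monotonicity in
the true disorder.

## Pair correlation function

`pairCorrelation()` implements the standard shell-count estimator
$$ g(r) = \frac{n_n(r)}{2 \pi r \, \Delta r \, \rho}, $$
with $n_n(r)$ the mean number of neighbours per particle in the annulus
of width $\Delta r$ at $r$, and $\rho = N/A_{box}$. Conventions: ordered
pairs (each unordered pair counts once from each end), self-pairs
excluded, $r$ evaluated at bin centres, bins $((b-1)\Delta r, b\Delta r]$.
Defaults: $\Delta r = \langle 2r_{hex}^{vor}\rangle/20$ — fine enough to
resolve the split second shell without empty bins at a few hundred
points — and $r_{max} = \min(5\,\langle 2r_{hex}^{vor}\rangle,$ half the
shorter window side$)$.

**Edge correction.** By default there is none, matching how such curves
are usually shown for micrograph data; the uncorrected estimator decays
at large $r$ because neighbours outside the window are missing (the bias
factor is roughly $1 - 4r/(\pi L)$ in an $L \times L$ window). An
isotropic correction (`edgeCorrection = TRUE`) weights each ordered pair
by the inverse fraction of the circle through the neighbour that lies
inside the window, computed in closed form for rectangles. The flatness
check $g \approx 1$ for CSR at several mean spacings only holds with the
correction on; with it off the same test documents the expected downward
bias.

**Small samples and bootstrap smoothing.** With a few hundred particles,
single pair separations produce spurious single-bin spikes.
`bootstrapPairCorrelation()` shakes the pattern `nRealizations` times
with an isotropic Gaussian of per-axis scale `sigma` — the positional
measurement uncertainty, e.g. half a pixel width — and averages the
per-realization estimates. Displacements are always drawn about the
observed positions (never chained), and realizations are clamped to the
window so every derived quantity keeps its window invariants. At
$\sigma \to 0$ the estimate converges to the raw one; between seeds, the
average of $n$ realizations fluctuates as $1/\sqrt{n}$ (at $n = 1000$
two seeds agree within about 1% of the peak; the test suite runs
$n = 200$ and uses the correspondingly scaled bound of 5%).

**Normalization and comparison.** `normalizeDistance()` rescales
distances by a spacing (usually $\langle 2 r_{hex}^{vor}\rangle$), so
samples of different density share a frame with the first-neighbour peak
at 1; `normalizeHeight()` scales the maximum to 1. A state machine
forbids double distance-normalization. `hexagonalReferenceGr()` is the
ideal-lattice reference in this frame: impulses at the triangular-lattice
shell distances $1, \sqrt3, 2, \sqrt7, 3, \dots$ with multiplicities
$6, 6, 6, 12, 6, \dots$, each deposited into a single bin and scaled by
the same shell-area denominator (with $\lambda = 2/\sqrt3$, the density
of the unit-spacing lattice). The split second shell — $\sqrt3 \approx
1.73$ and exactly 2 — is the fingerprint of hexagonal order. Broadened
references are obtained by running the estimator on `hexaticEnsemble()`
output instead; impulse references are never artificially broadened.

`differenceSpectrum()` subtracts a reference from a sample (both must be
distance- and height-normalized; the reference is linearly interpolated
onto the sample's bins, never extrapolated), and `deltaRms()` condenses
the residual to a single number. The RMS of $\Delta g$ over the compared
range is the implemented definition (recorded in every run manifest); it
is zero for identical curves, $|c|$ for a constant offset $c$, maximal
among the tested classes for CSR against a lattice reference, and grows
monotonically with the hexatic jitter scale.

## Minkowski bond order parameters

For particle $i$ with Voronoi-facet neighbours at azimuths $\phi_b$,
$$ q_\ell(i) = \Big[\tfrac{4\pi}{2\ell+1} \sum_{m=-\ell}^{\ell}
   \big|\textstyle\sum_b w_b Y_{\ell m}(\tfrac{\pi}{2}, \phi_b)\big|^2
   \Big]^{1/2}. $$
The 2D embedding places all bonds in the equatorial plane of the
spherical-harmonic frame (polar angle $\pi/2$, azimuth = bond angle
from +x) — the standard planar reduction, which makes $q_\ell$ a
function of bond azimuths only and manifestly invariant under rigid
rotations (the $m$-sum sees a rotation as a phase). The harmonics are
orthonormalized with the Condon–Shortley phase; the phase squares away,
so any consistent convention gives identical values (verified by a
rotation-invariance test at $10^{-10}$).

Weights: `"facet"` mode (the Minkowski variant, default) uses
$w_b = p_b / \sum p$, the normalized Voronoi facet lengths — neighbours
subtending metastable sliver facets contribute proportionally little,
which removes the main artifact of the raw coordination count (a jittered
square lattice reads as coordination ~6, but its sliver facets carry
negligible weight, so $q_4$ still identifies the square symmetry).
`"uniform"` mode uses $1/n$ and coincides with facet mode whenever all
facets are equal. Weights sum to one per particle; $0 \le q_\ell \le 1$;
a single bond gives $q_\ell = 1$ in every basis (the spherical-harmonic
addition theorem makes the single-direction sum direction-independent).

Normalization: $q_\ell^{sym}$ is the value for $\ell$ equally weighted
bonds at arc spacing $2\pi/\ell$ — the highest-symmetry configuration in
that basis. `qSym()` computes it numerically through the same kernel on
first use and caches it (no table of constants); the perfect hexagonal
lattice then scores exactly 1 in $\ell = 6$, the perfect square lattice
exactly 1 in $\ell = 4$. Edge particles are excluded from
$\langle q_\ell \rangle$ by default since their facet sets are truncated
by the window. For disordered (CSR-like) patterns the normalized means
converge to a similar value in every basis $\ell = 4..7$ — the spread
across bases being smaller than the distance of any of them to 1 is the
package's operational signature of "no preferred symmetry".

## Entropic valence maps

`bondCloud()` translates every included particle to the origin together
with its neighbour displacement vectors (one vector per retained facet,
so the pooled count equals the summed coordination numbers), optionally
keeping only particles of one coordination number — the tool for asking
whether 5- and 7-fold disclinations are randomly scattered or organized
along grain boundaries. `orientClouds()` rigidly rotates each cloud so a
reference bond points along +y; the reference is the neighbour with the
longest facet (the most strongly "bonded" one) by default, or the first
bond counter-clockwise from +x. The underlying data carries no intrinsic
orientation convention, so the rule is deterministic, switchable, and
recorded with every oriented map. `probabilityMap()` histograms the
pooled endpoints into an $n \times n$ grid over $[-R, R]^2$ (default
$R = 2\,\langle 2 r_{hex}^{vor}\rangle$), normalized to total probability
one; counts are deposited as unit weights — smoothing is a rendering
concern, not a data concern. A hexagonal sample shows six sharp maxima at
$2\pi/6$ arcs; CSR shows an angularly uniform ring.

## Synthetic generators: what they emulate, and what not

The generators exist so every metric is testable without external data;
they emulate the study conditions of a typical AFM micelle series
(hundreds of points per window, hexagonal base symmetry, positional
uncertainty of order one pixel).

* `hexagonalLattice()` / `squareLattice()` — ideal references matched to
  a target intensity; spacing $(2/(\lambda\sqrt3))^{1/2}$ resp.
  $\lambda^{-1/2}$. Sites come from an extended grid anchored at the
  window centre and cropped, so patterns are translation-stable under
  window resize; the realized count is within one row/column of
  $\lambda A_{box}$.
* `hexaticEnsemble()` — the tunable crystal-to-liquid reference:
  independent isotropic Gaussian displacements of per-axis scale
  $\Delta r$ about the base positions. A stated displacement scale of
  "half a pixel width" is read as per-axis standard deviation
  `pixelSize/2` (a variance with length units would be ill-formed).
  Realizations are clamped to the window; the clamp is only active
  within a few $\Delta r$ of the boundary.
* `csrPattern()` — homogeneous Poisson process: the fully disordered
  limit.
* `confinedPacking()` — a qualitative fixture for hard-wall confinement:
  soft linear repulsion within 1.8 mean spacings, fixed step, wall
  clamping, iteration-capped. It reliably produces ordered wall-aligned
  rows around a frustrated interior. **Known limitation:** it does not
  spontaneously develop a central square-ordered domain the way a
  genuine confined-packing simulation can; claims that depend on that
  morphology are not asserted anywhere.

All stochastic generators take an explicit integer seed and restore the
caller's RNG state; there is no hidden global state, which is what makes
run manifests sufficient for bit-identical reproduction.

What passing tests on these generators shows about real data — and what
not: the generators produce stationary, isotropic, unimodal patterns.
Real micrographs add polycrystallinity, anisotropic drift, detection
errors (missed/spurious particles) and polydispersity, none of which the
generators model. The metrics are well-defined on such data, but the
parameter-recovery calibrations quoted here are specific to the
generator's noise model.

## Numerical choices, degenerate inputs, problem sizes

* Duplicate points (within $10^{-12}$ of the window diagonal) are an
  error, not merged: a tessellation with coincident generators is
  undefined.
* Tessellation needs $N \ge 2$; disorder estimation $\ge 3$ buffered
  interior cells; every analysis needs $N \ge 1$.
* $r_{max}$ beyond half the shorter window side warns and proceeds.
* The bin containing an exact lattice distance is decided by floating
  rounding at the bin edge; peak positions are therefore always reported
  as intensity-weighted centroids over contiguous above-threshold bins,
  which is stable to half a bin.
* Test and example problem sizes were chosen as the smallest at which
  each asymptotic claim is comfortably inside its tolerance: lattices of
  ~200–1300 sites for identities, CSR of ~2500–5000 points for the
  disorder limits (the 5000-point case mirrors the classic disordered
  benchmark), bootstrap ensembles of 200 realizations.

## Limitations

Rectangular windows only (no polygonal masks); unweighted tessellations
(polydisperse radii are carried as metadata, not used as Laguerre
weights); no structure factors or FFT-based metrics; no 3D variants. The
orientation rule for valence maps and the edge-correction choice for
$g(r)$ are conventions — both are recorded in run manifests precisely
because results can depend on them.
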