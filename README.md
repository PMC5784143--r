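# PlanarOrder

Quantitative order metrics for two-dimensional dispersions of objects —
block-copolymer micelles, nanoparticles, colloids, quantum dots, cells —
observed as centroid coordinates in a bounded window (typically extracted
from AFM/SEM/optical micrographs with an image-analysis tool). Visually
similar dispersions often differ systematically in their degree and
*kind* of order; PlanarOrder separates and quantifies three kinds:

| Kind of order | Global observable | Local reference | Disorder / confidence |
|---|---|---|---|
| translational | pair correlation $g(r)$, first-peak position | expected hexagonal spacing $\langle 2r_{hex}^{vor}\rangle$ | lattice disorder parameter $\Delta r$, residual $\Delta_{rms}$ |
| entropic | coordination histogram | Voronoi tessellation, 5\|7 disclinations | valence (first-neighbour) probability maps |
| angular | $\langle q_6\rangle / q_6^{sym}$ | $\ell$-fold bond order $\langle q_\ell\rangle / q_\ell^{sym}$ | spread of normalized $q_4..q_7$ |

At the core:

* **Pair correlation** $g(r) = n_n(r) / (2\pi r \Delta r \rho)$ with
  optional bootstrap smoothing for small samples (the pattern is shaken
  by the positional measurement error and the ensemble averaged),
  distance normalization to the mean spacing, height normalization,
  impulse reference for the ideal triangular lattice (split second shell
  at $\sqrt3$ and 2 normalized diameters), difference spectra
  $\Delta g(r)$ and their RMS.
* **Window-clipped Voronoi tessellation** whose cell areas tile the
  window to relative $10^{-9}$: coordination numbers with degenerate
  facet filtering, local hexagonal radii
  $r_{hex} = \sqrt{A_{vor}}(2\sqrt3)^{-1/2}$, the mean expected spacing
  $\langle 2r_{hex}^{vor}\rangle$, and the lattice disorder parameter in
  two forms ($\sqrt{\mathrm{Var}(r_{hex})}$ and first-order error
  propagation through the spacing function).
* **Minkowski bond order parameters** $q_\ell$ for any symmetry basis,
  with Voronoi-facet-length weighting and numerically computed
  perfect-symmetry references $q_\ell^{sym}$.
* **Entropic valence maps**: neighbour displacement clouds pooled at a
  common origin, optionally subset by coordination and rotated to a
  common orientation, histogrammed into probability maps.
* **Synthetic generators** (hexagonal/square lattices, Gaussian-jittered
  hexatic ensembles, CSR, a confined-packing fixture) so every metric is
  testable without external data.

## Worked example

Simulate a micelle-like sample — a hexagonal lattice at 100 nm spacing in
a 2 µm window, with 8 nm of Gaussian positional disorder — and run the
combined report:

```r
library(PlanarOrder)
w <- obsWindow(0, 2000, 0, 2000)              # nm
lam <- 2 / (sqrt(3) * 100^2)                  # intensity of a 100 nm lattice
sample <- hexaticEnsemble(hexagonalLattice(lam, w),
                          deltaR = 8, nRealizations = 1, seed = 42)[[1]]
orderReport(sample, reference = "hexagonal")
#> OrderReport: 1 sample(s)
#>    label   N    lambda meanSpacing deltaR deltaRPropagated p5 p6 p7
#> 1 ...     471 0.0001178       99.99  1.614            1.612  0  1  0
#>   q4Norm q5Norm q6Norm q7Norm deltaRms
#> 1 0.4839 0.3149 0.8657 0.3855   0.3806
```

Reading the row: 471 particles at intensity 1.18·10⁻⁴ nm⁻²; the Voronoi
route recovers the mean spacing ⟨2r_hex^vor⟩ = 99.99 nm without measuring
a single distance; the two Δr estimators agree (1.614 vs 1.612 nm of
local spacing spread); every interior particle still has 6 Voronoi
neighbours (p6 = 1, no disclinations at this jitter); the normalized bond
order is high in the 6-fold basis (0.87) and low in 4/5/7 — an ordered,
specifically hexagonal, sample; Δ_rms = 0.38 is its residual against the
ideal hexagonal g(r) reference. Per-metric objects are available
individually:

```r
part <- tessellate(sample)
disorderEstimate(part)
#> DisorderEstimate (313 interior cells)
#>   <2 r_hex^vor> = 99.988
#>   delta-r: 1.61378 (variance form), 1.61231 (error propagation)
bondOrder(part, 6)
#> BondOrderResult l = 6 (facet weights): <q_6> = 0.6413, q_sym = 0.7408, normalized 0.8657
#>   389 of 471 particles in the mean
```

Real data enters through `readPattern("centroids.csv", pixelSize = 2.44)`
(CSV/TSV/dat/xls; first two numeric columns are x,y; header rows are
auto-skipped; the pixel size converts to physical units once, at read
time).

## Documentation

The methods vignette (`vignettes/quantifying-2d-order.Rmd`) documents the
models, conventions (edge handling, facet degeneracy filtering, the 2D
spherical-harmonic embedding, orientation rules), parameter defaults, and
known limitations.
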