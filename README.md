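# aratile

Tools for simulating and quantifying multicellular tile patterns.

Columns in the fly visual centre — the cylindrical functional units built
by the R7, R8 and Mi1 neurons — arrange their 2D centre coordinates in
patterns between hexagonal and tetragonal.  `aratile` provides, in one
tested package:

* a nonlocal aggregation–diffusion **population model** in which cells
  interact through short-range **a**dhesion, medium-range **r**epulsion and
  long-range **a**ttraction (ARA), solved by an explicit upwind
  finite-volume scheme on a periodic square domain, as a single-species
  model and as the coupled R7/R8/Mi1 three-species system;
* the companion **pattern analysis**: cluster-centre extraction from
  density fields, NBH-1/2/3 neighbourhood angle statistics, and symmetry
  indices obtained by fitting the angle ECDF of a pattern against a library
  of perturbed regular lattices;
* **experiment drivers** for single-kernel reference runs, parameter sweeps
  over the R7–R7 kernel, and band summaries emulating
  reduced/control/enhanced adhesion comparisons.

## The model

For one population with density $u(x,t)$ on $(-L,L)^2$ (periodic):

$$\partial_t u = \nabla\cdot(u\nabla u) - \nabla\cdot\big(u(1-u)K(u)\big),
\qquad K(u)(x) = \int_{|y|\le 1} u(x+y)\,\omega(|y|)\,\tfrac{y}{|y|}\,dy,$$

with the piecewise-constant kernel
$\omega(r) = F_0$ on $[0,R_0)$, $F_r$ on $[R_0,R_1)$, $0$ on $[R_1,R_2)$
(the *terrace*), $F_a$ on $[R_2,1)$, $0$ beyond the sensing radius 1.
The width of the terrace selects the emergent cluster lattice: a narrow
terrace favours triangular packing, a wide one tetragonal.  The
three-species system couples $u,v,w$ through a symmetric kernel matrix with
pressure and saturation acting on the total density $\sigma=u+v+w$.

A pattern's **Index-k** is the row-height $h^*$ of the centered-rectangular
lattice family (square at $h=1/2$, triangular at $h=\sqrt3/2\approx0.866$)
whose perturbed angle distribution best matches the pattern's NBH-k angle
ECDF in $L^2(0,\pi)$:

$$(h_k^*, p_k^*) = \mathrm{argmin}_{0.5\le h\le 1,\ 0\le p\le p_{max}}
\;\|F_k^{data} - F_k(\cdot;h,p)\|_{L^2(0,\pi)} .$$

## Worked example

Classify a synthetic column pattern:

```r
library(aratile)

pts <- perturb_points(generate_lattice(h = 0.65, rows = 12, cols = 12,
                                       wrap = TRUE), p = 10, seed = 1)
fit <- symmetry_fit(pts, k = 3, pmax = 20)
fit
#> symmetry fit (NBH-3): Index-3 = 0.6500, p* = 11%, E = 0.006378
#>   pattern: nearer tetragonal (h = 0.5 tetragonal, 0.8660 hexagonal)
#>   975 angles pooled from 144 interior particles; pmax = 20
```

The fitted height 0.65 recovers the generating lattice exactly and the
fitted disturbance sits within a point of the injected 10%; `E` is the L2
distance between the two angle CDFs (`plot(fit)` overlays them).  An index
near 0.5 means tetragonal order, near 0.866 hexagonal.

Simulate a single-species pattern and classify its clusters:

```r
res <- run_single_species("A", N = 128)   # disk initial condition,
res$fit                                   # upwind solve, centre extraction
#> symmetry fit (NBH-3): Index-3 = 0.7000, p* = 30%, E = 0.047298
#>   pattern: nearer hexagonal (h = 0.5 tetragonal, 0.8660 hexagonal)
#>   160 angles pooled from 24 interior particles; pmax = 30
```

Variant A (narrow terrace) relaxes to clusters nearer triangular packing;
variant B (wide terrace) gives an index on the tetragonal side (0.68 at
this resolution, against 0.70 for A).  Note the large fitted disturbance:
emergent patterns at desk-scale resolution are polycrystalline, so indices
should be compared between conditions rather than read absolutely.

A command-line front end wrapping these functions lives at
`inst/cli/ara.R` (`simulate`, `analyze-points`, `make-reference`,
`sweep`).

## Package layout

* `R/kernels.R` — ARA kernels, interaction matrix, config IO
* `R/grid.R`, `R/solver.R`, `src/solver.cpp` — grids, states, nonlocal
  term, upwind finite-volume integration (FFTW-backed)
* `R/points.R` — point sets, cluster-centre extraction, rescaling
* `R/lattice.R` — lattice family, perturbations, reference libraries
* `R/symmetry.R`, `src/angles.cpp` — NBH angle statistics and the index fit
* `R/experiments.R` — reference runs, sweeps, band summaries
* `vignettes/ara-tile-patterns.Rmd` — model, numerics and design notes
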