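# branchscale

Measure how branch thickness scales in trees — real, simulated, carved,
or painted.

## The problem

Idealised trees are self-similar: every ramification splits a bough of
radius *r<sub>c</sub>* into boughs *a* and *b* whose radii satisfy

> *r<sub>a</sub><sup>α</sup> + r<sub>b</sub><sup>α</sup> = r<sub>c</sub><sup>α</sup>*

for a single **radius scaling exponent α**. α = 2 is the classical
area-preserving rule (combined cross-section conserved across
branching); α = 3 is Murray's law, optimal for fluid transport; measured
woody plants mostly fall between about 1.5 and 3. The same exponent
counts branches — a tree with trunk radius *r₀* carries roughly
*n* = (*r₀*/*r*)<sup>α</sup> branches of radius about *r* — which means
the diameter of a randomly chosen branch follows a power law with tail
*P*(*d* ≥ *x*) = (*x<sub>m</sub>*/*x*)<sup>α</sup>. That is what makes α
measurable from a flat list of branch diameters, with no record of the
branching topology: overlay line segments on an image, one per branch
diameter, and fit the list.

`branchscale` is for anyone who needs that number: plant allometrists
comparing crowns to transport-optimality predictions, image analysts
scoring annotated photographs or artwork, and graphics people who want
procedurally generated trees with controlled proportions. It provides:

* **Scaling mathematics** — `complete_triplet()` solves branch
  proportions in closed form, `branch_count()` the count law,
  `check_flow_conservation()` verifies conservation of *r*<sup>α</sup>
  across every transect of a tree.
* **A seeded tree generator** — `generate_tree()` grows random
  self-similar trees obeying the radius relation exactly at every
  ramification (and its length analogue with exponent β), with
  `sample_diameters()` for direct Pareto draws and `tree_to_diameters()`
  to emulate noisy hand annotation.
* **Annotation input** — `read_svg_annotations()` extracts diameter
  marks (straight line segments, with affine transforms and per-observer
  layers) from SVG overlays; `read_csv_diameters()` reads plain lists.
* **The estimator** — `log_bin()` bins diameters by powers of λ
  (default 2) above a cutoff *x<sub>m</sub>*; `fit_alpha()` applies the
  closed-form maximum-likelihood estimator
  α̂ = ln(1 + N/S)/ln λ; `fit_powerlaw()` adds a seeded bootstrap
  confidence interval; `tail_curve()` and `threshold_diagnostic()`
  check that the cutoff excludes small-scale curvature.
* **Fractal dimension** — `rasterize_tree()` renders a tree to a
  256×256 binary image and `box_count_dimension()` estimates D as the
  regression slope of log₂ N on log₂ (boxes across), the relation
  N = (1/r)<sup>D</sup>.

## Worked example

Fit the scaling exponent from an annotated SVG overlay (the package
ships a small synthetic example with two observer layers):

```r
library(branchscale)
fixture <- system.file("extdata", "synthetic_annotation.svg", package = "branchscale")
obs_a <- read_svg_annotations(fixture, layer = "observer-A")
#> Diameter sample: 60 branches [cm], synthetic_annotation.svg (observer-A)
#>   range 0.2036 .. 0.9532, median 0.2596

analyze_sample(obs_a, xm = 0.2, n_boot = 10000, seed = 1)
#> Scaling analysis of synthetic_annotation.svg [observer-A] (n = 60, unit cm)
#> Power-law tail fit: alpha = 2.939  (95% CI 2.248 .. 4.392)
#>   xm = 0.2, lambda = 2, n = 60 used, 0 below xm
#>   cutoff diagnostic: local tail slope -2.895 vs -alpha -2.939 -> ok
```

Reading: the 60 annotated diameters are consistent with self-similar
scaling at α̂ ≈ 2.9 — near Murray's law — with a wide interval, as
expected from 60 marks; the diagnostic confirms the tail curve's slope
at the cutoff matches the fit, so *x<sub>m</sub>* = 0.2 cm excludes no
usable data. The sample was in fact drawn with true α = 2.5, inside the
interval.

Generate a tree and measure its fractal dimension:

```r
tree <- generate_tree(alpha = 2.5, seed = 1)
#> Self-similar branching tree: 999 branches (500 terminal), 15 generations
#>   alpha = 2.5, beta = 2.5, stop_ratio = 0.1, asymmetry in [0.6, 1], seed = 1
#>   radius range 0.05631 .. 1 (contrast 17.8-fold)
box_count_dimension(rasterize_tree(tree))
#> Box-counting dimension D = 1.5937 (R^2 = 0.9997) over 8 grids
```

A shell front end wrapping the same functions lives at
`system.file("scripts", "branchscale.R", package = "branchscale")`, with
subcommands `analyze`, `simulate` and `boxcount`.

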