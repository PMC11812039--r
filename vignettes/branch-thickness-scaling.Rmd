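---
title: "Branch-thickness scaling: model, estimator, and measurement choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branch-thickness scaling: model, estimator, and measurement choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(branchscale)
```

## The model

A tree is self-similar in branch thickness when a single exponent
$\alpha$ is preserved at every ramification: a bough of radius $r_c$
splitting into boughs of radii $r_a$ and $r_b$ satisfies

$$r_a^\alpha + r_b^\alpha = r_c^\alpha.$$

The exponent has a physical reading. If the flow carried by a branch is
$f = c\,r^\alpha$ for some constant $c$, then conservation of flow across
any *transect* — a cut separating all leaves from the root exactly once —
forces the relation above, because two transects that differ only in
whether they cross a parent or its two children must carry the same total
flow. $\alpha = 2$ preserves cross-sectional area (the classical
area-preserving rule); $\alpha = 3$ is Murray's law, the optimum for
laminar fluid transport; measured woody trees mostly fall between
roughly 1.5 and 3. The constant $c$, and with it every unit conversion
(including radius versus diameter), cancels from all equations — which is
why the package treats radii and diameters interchangeably and why all
estimation is scale-free.

Carrying the transect argument one step further counts branches: a
self-similar tree with trunk radius $r_0$ has approximately

$$n = (r_0 / r)^\alpha$$

branches of radius about $r$. Two consequences drive everything else in
the package. First, the diameter of a randomly selected branch follows a
power law with tail $P(d \ge x) = (x_m/x)^\alpha$, so $\alpha$ can be
estimated from a flat, topology-free list of diameters — no record of
which diameter belongs to which branch is needed, which is what makes
hand annotation of artwork or photographs practical. Second, $\alpha$
controls how much fine detail a figure accumulates: per ramification the
branch count doubles while radii shrink by factors near $2^{-1/\alpha}$,
so a higher $\alpha$ packs exponentially more branches into the same
radius contrast, which in turn raises the box-counting dimension of the
rendered figure.

## The generator

`generate_tree()` is the package's synthetic-data source and its defaults
are the study conditions for every simulation-based test. It grows a
binary tree from one trunk; at each ramification it draws the
smaller-to-larger child ratio $u$ uniformly on
`[asymmetry_low, asymmetry_high]` and solves the triplet relation in
closed form (`complete_triplet()`), so the radius relation holds exactly
— to floating point — at every split. Lengths obey the analogous relation
with their own exponent $\beta$, reusing the same $u$ so that slimmer
children are also shorter; this is the simplest coupling consistent with
the sum constraint, which by itself does not fix how the split is shared.
Subdivision stops once a branch's radius falls below
`stop_ratio * trunk_radius` (the branch is kept), giving a radius
contrast of roughly `1/stop_ratio` across the tree.

Default values, and why:

* `stop_ratio = 0.1` — a 10-fold radius contrast, the regime in which
  differences in $\alpha$ become visually and statistically prominent.
* `asymmetry_low = 0.6, asymmetry_high = 1` — ramifications in real
  crowns are rarely more lopsided than roughly 3:5; the range includes
  the symmetric case. Setting both to 1 recovers exactly symmetric
  trees, used wherever a test needs exact terminal counts.
* `branch_angle = 0.35`, `angle_jitter = 0.15` (radians) — produces
  natural-looking crowns. Geometry influences only rendering and the
  box-counting dimension, never the diameter statistics.
* `trunk_radius = 1`, `trunk_length = 10` — a slenderness typical of a
  young open-grown stem; the ratio matters only for rendered dimension.
* `max_branches = 1e6` — a budget that converts runaway recursion from a
  hang into an error.

Random draws are consumed depth-first, child-a-first ($u$, then the two
angular jitters, then the first child's subtree), so a parameter set plus
seed reproduces a bit-identical branch list; the generator restores the
caller's RNG state.

What the generator deliberately does *not* emulate: curvature and taper
along a limb, overlap and occlusion, bark texture, leaves, damage,
coppicing, or any deviation from exact self-similarity other than
multiplicative annotation noise (`tree_to_diameters(noise_cv = )`,
lognormal with median 1). Passing recovery tests on these trees therefore
demonstrates correctness of the estimator under the model, not robustness
to the many ways real artwork and real trees violate it — systematic
curvature in the tail plot is precisely the situation the cutoff
diagnostic exists to catch.

## The estimator

Diameters at or above a cutoff $x_m$ are binned logarithmically: bin $k$
covers $[x_m\lambda^k, x_m\lambda^{k+1})$, with $\lambda = 2$ by default.
Binning absorbs within-scale measurement noise; the tail law implies the
bin index is geometric,

$$\Pr(k) = (1 - \lambda^{-\alpha})\,\lambda^{-\alpha k},$$

whose maximum-likelihood estimator is closed-form:

$$\hat\alpha = \frac{\ln(1 + N/S)}{\ln \lambda},$$

with $N$ the retained count and $S$ the sum of bin indices. The tests
verify this formula against brute-force maximisation of the binned
likelihood. Note the convention: $\hat\alpha$ is the exponent of the
*cumulative* (tail) distribution — the negative slope of the log–log
exceedance curve and the exponent of the branching relations — not the
density exponent, which is larger by 1.

Numerical and procedural choices:

* **Bin boundaries.** Half-open bins, boundary values go up; the bin
  index snaps $\log_\lambda(d/x_m)$ to the nearest integer within a
  relative $10^{-12}$ before flooring, so diameters constructed to sit on
  a boundary are stable against floating-point drift.
* **Cutoff $x_m$** is a per-dataset input, not a fitted quantity: data
  below it are censored or unreliable (brush width, carving limits, an
  annotator's decision that a stroke is too thin to mark) and retaining
  them biases $\hat\alpha$ downward. `threshold_diagnostic()` implements
  the standard visual check numerically: the local log–log slope of the
  tail curve within the first bin above $x_m$ should match $-\hat\alpha$;
  a deviation beyond 25 % flags the cutoff. `choose_xm()` scans distinct
  diameters for the smallest unflagged cutoff but is deliberately labelled
  non-canonical — inspection of the work and its tail curve comes first.
* **Confidence intervals** are nonparametric bootstrap percentile
  intervals (default 10,000 resamples, seeded). Because $\hat\alpha$
  depends on the data only through the bin counts, each resample is drawn
  as one multinomial over the observed counts — distributionally
  identical to resampling diameters with replacement. Degenerate
  resamples (all mass in bin 0, $\hat\alpha$ unbounded) are redrawn with
  a cap and reported. Coverage at the study conditions (true
  $\alpha = 2$, $x_m = 1$, $n$ in the hundreds) is near nominal; the test
  suite checks it stays at or above 85 % for 95 % intervals.
* **Degenerate inputs.** A sample entirely below $x_m$, or entirely
  within the first bin ($S = 0$), raises an informative error rather
  than returning an infinite estimate. Replicates are fitted separately;
  pooling across observers is an explicit choice left to the caller.

## Annotation input

`read_svg_annotations()` reads the overlay convention used for
morphometric scoring in a vector editor: each straight line segment,
drawn perpendicular to a branch, records one diameter. The reader
accepts `<line>`, two-point `<path>` (absolute, relative, `H`/`V`, and
implicit line-to dialects) and two-point `<polyline>` elements, composes
all ancestor affine transforms, and filters the rest: curved paths are
counted and skipped, zero-length segments excluded by name. Groups
(`id` or `inkscape:label`) select observer replicates. Lengths are
reported in user units unless an explicit scale is given or the document
declares a physical width with a viewBox — legitimate either way, since
the estimate is scale-invariant (the tests check bit-identical bin
indices under any common rescaling).

## Rasterisation and box counting

`rasterize_tree()` draws each branch as a filled capsule (round-capped
stroke of width equal to the branch diameter) on a power-of-two grid,
256×256 by default, with exact point-in-capsule tests at pixel centres —
no anti-aliasing, so occupancy is binary and deterministic.
`box_count_dimension()` covers the image with dyadic grids of
$2^1 \ldots 2^{\log_2 \mathrm{size}}$ boxes across and estimates $D$ as
the OLS slope of $\log_2 N$ against $\log_2 g$, the scaling relation
$N = (1/r)^D$. Grids are anchored at the image origin (no offset
averaging — the plain construction); the single-box grid is excluded
because $N = 1$ identically. On exactly affine data the regression is
exact: a full image gives $D = 2$, a one-pixel line $D = 1$, a single
pixel $D = 0$, to machine precision. For rendered trees $D$ increases
with $\alpha$ at fixed seed and geometry, but $D$ also responds to
$\beta$ and to the radius-to-length ratio, which is why $\alpha$ — a
property of the diameters alone — is the more interpretable quantity.

## Problem sizes in the test suite

The suite favours the smallest sizes at which each property is sharp:
Pareto recovery runs at $n = 500$ with 200 replicates per exponent and
1,000-resample intervals; tail-convergence checks use $n = 10^5$ draws;
λ-robustness uses $n = 1000$; trees use the default 10-fold contrast
(about 30 to 3,000 branches for $\alpha$ from 1 to 3). These were chosen
as the scale of the data the method is designed for — annotated artworks
yield tens to a few hundred diameters per replicate.

## Known limitations

* The estimator assumes independent draws from a single power law;
  diameters from one tree are a finite, dependent population, and the
  truncation at the generator's stop radius bends the tail below the
  stop diameter — fits on simulated trees should set $x_m$ at or above
  `2 * stop_ratio * trunk_radius`.
* `choose_xm()` can settle on a cutoff that still carries bias when
  curvature is gradual; it is a convenience, not an inference procedure.
* The box-counting dimension of a rendering depends on stroke style,
  margins and resolution; only comparisons holding those fixed are
  meaningful.
* The SVG reader handles straight-segment dialects and affine
  transforms, not CSS-styled geometry, `use` references, or curved
  annotation conventions.
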