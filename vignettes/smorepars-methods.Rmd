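---
title: "Calibrating an agent-based vascular tumor model through an ODE surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating an agent-based vascular tumor model through an ODE surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Agent-based models (ABMs) of tumor growth are expensive to simulate and
awkward to calibrate: bulk experimental data (tumor-volume time-courses
from xenograft studies) constrain only aggregate behavior, while the ABM's
parameters act at the single-cell level. `smorepars` implements a
surrogate-model calibration strategy (SMoRe ParS) that routes all inference
through an explicitly formulated ODE *surrogate model* (SM):

1. choose the SM formulation from the structure of the data (a single ODE
   for volume time-courses);
2. simulate the ABM over a grid of its parameters of interest, several
   replicates per grid node;
3. select the SM among candidate growth laws by information criteria;
4. fit the SM to each node's replicate-averaged output, quantify the
   uncertainty of each SM parameter by profile likelihood, and interpolate
   the per-node 95% bounds into lower/upper *confidence hypersurfaces* over
   the ABM parameter plane;
5. fit the SM to the experimental data, profile it there, and extract the
   practically identifiable combination of SM parameters;
6. project every data-admissible SM parameter choice back through the
   hypersurfaces, intersect per-parameter regions, and take the union over
   admissible choices: the ABM parameter region consistent with the data.

SM parameters act as interlocutors: they can be estimated from data *and*
mapped onto ABM inputs, which neither side can do directly.

# The agent-based model

The ABM is a 3D, two-grid, on-lattice model of stem/progenitor-driven
vascular tumor growth in a 1 mm cube. Cells live on a 50^3 lattice (20 um
spacing); vessels on a 10-fold finer 500^3 lattice (2 um), reflecting
microvessel diameters below the cell scale.

**Tumor module.** Cells are stem or progenitor. Stem cells divide with
probability 0.05 per iteration, symmetrically (two stems) with probability
0.05, else asymmetrically (stem + progenitor); they have unlimited
replicative potential. Progenitors divide with probability `p_div` up to
`div_lim` times — parent and daughter share the incremented division count
(symmetric division) — then become senescent, remain on the lattice
(continuing to block space) and die with probability 0.1 per iteration.
Daughters are placed in a uniformly chosen empty Moore (26-cell) neighbor
site; a fully surrounded cell simply fails to divide, which is the spatial
inhibition that ultimately saturates growth. Each daughter is
high-migratory with probability 0.05. Cells random-walk with expected step
count `rate x 6 h / 20 um` per iteration (8.3 um/h high, 0.83 um/h low;
the fractional part realised as a Bernoulli extra step; each step draws one
of the 26 directions uniformly and is rejected at occupied or out-of-bound
targets). One iteration represents 6 hours; baseline simulations run 300
iterations (75 days). The tumor starts as 20 stem + 80 progenitor cells
packed into the 5 x 5 x 4 corner sites, stem cells interleaved evenly.

**Vasculature module.** Eight straight mature vessels run along the three
boundary faces adjacent to the tumor corner; mature vessels are perfused
from the start. Cells within `oxygen_radius` (100 um, a classic oxygen
diffusion length) of a perfused vessel site are normoxic; the rest are
hypoxic, halving their division probability (`hypoxic_div_factor` = 0.5)
and migrating at the high rate. Hypoxic cells recruit vessels: each mature
fine-lattice site attempts one sprout per iteration with probability
`max_branch_prob x (1 - d/vegf_radius)` where `d` is the distance to the
nearest hypoxic cell (maximum 0.2 at contact, zero beyond
`vegf_radius` = 200 um). Sprout tips advance 20 um per iteration along the
discrete ray toward the nearest cancer cell (lexicographic tie-break) and
fuse — anastomose — with any other vessel site within 20 um, excluding
their own chain and the immediate neighborhood of their own branch point.
A closed chain carries blood when both of its attachment objects connect to
the mature network through the graph of mature vessels and closed chains;
open sprouts never do. Perfusion only ever grows (no vessel pruning), so
the oxygenation mask is maintained incrementally and exactly.

Two readings of "one branch attempt per mature segment" were possible:
per whole vessel (8 attempts/iteration) or per unit fine-lattice segment.
The per-vessel reading produces a sparse, quasi-one-dimensional network
whose box-counting dimension (~1.2) is inconsistent with the dense
space-filling vasculature this family of models is known to produce
(replicate-averaged dimensions near 1.9-2.0, matching measurements on
whole-tumor xenograft vessel casts); the per-segment reading is also the
one implied by defining vessel segments as unit lattice bonds. The
per-segment rule is implemented.

`p_div` (0.05-0.245) and `div_lim` (8-15) are the calibration parameters:
the bulk of a growing tumor is non-stem cells, so progenitor proliferation
dominates volume dynamics, and two parameters keep the proof of concept
visualisable. The sampled design is the 3 x 3 grid
{0.05, 0.125, 0.245} x {8, 12, 15}; configuration defaults sit at the
interior node (0.125, 12).

# Surrogate growth laws

Three classical candidates are implemented for the total size `N(t)`:

* generalized Gompertz: `dN/dt = N^lambda (delta - gamma log N)`
* generalized logistic: `dN/dt = gamma N (1 - (N/K)^lambda)`
* von Bertalanffy (vB): `dN/dt = alpha N^gamma - beta N`

`sm_solve()` integrates any of them with `deSolve` (lsoda, rtol 1e-8,
atol 1e-10). Fitting loops use exact fast paths instead: the vB equation is
a Bernoulli ODE with closed form
`N^(1-gamma) = alpha/beta + (N0^(1-gamma) - alpha/beta) e^(-beta(1-gamma)t)`
(`|1-gamma| < 1e-6` routes to the exponential limit), the generalized
logistic reduces to a logistic in `u = (N/K)^lambda`, and the Gompertz
variant is integrated in log-space with guards that reject parameter
corners whose plateau exceeds `e^60` — those are never competitive fits and
only grind the integrator. Equivalence of fast paths and the generic solver
is asserted in the tests at relative error below 1e-6.

Model selection uses Gaussian concentrated-likelihood information criteria,
`AIC = n log(RSS/n) + 2k` and `BIC = n log(RSS/n) + k log n` (a
full-likelihood variant with the additive Gaussian constants is available;
constants cancel in comparisons). Scores against a family of ABM datasets
are aggregated by summing weighted RSS and `n` over the nodes with
`k = 3 x nodes`, giving one score per candidate. A caveat the test suite
quantifies: the generalized Gompertz family can reproduce von Bertalanffy
trajectories to about 4 parts in 10^4 relative RMS, far inside any
realistic noise floor, so vB-vs-Gompertz selection on vB-like data is
essentially uninformative; the generalized logistic misfits the same
curves at the percent level and is reliably distinguished. Decisive margins
require data *outside* all three families — which is exactly what ABM
output is.

An auxiliary constant-rate law (`lin`, `dN/dt = theta`) exists because its
weighted least-squares problem is linear-Gaussian with closed-form estimate
and standard error; it anchors the profile-likelihood machinery to analytic
results in the tests.

# Fitting and practical identifiability

All datasets are replicate means with standard errors (`growth_data`),
and fits minimise the weighted sum of squared residuals
`chi2 = sum_i ((z_i - y_i)/sigma_i)^2`. Standard errors are floored at
`1e-3 x max(z)` (replicate spread can be zero at early ABM time points).
`N0` is fixed at the first observation, so all three candidate laws have
exactly 3 free parameters. Optimisation is multi-start (20 Latin-hypercube
starts, log-uniform within per-parameter bounds), each start polished by
`L-BFGS-B` on log-parameters; the winner gets an additional derivative-free
polish (Nelder-Mead with a box penalty, Brent in one dimension) because
finite-difference gradients stall on the sloppy ridges these growth laws
produce.

Profile likelihood: the profiled parameter is fixed on a 41-point
log-spaced grid spanning a factor of ten either side of the estimate, the
remaining parameters re-optimised at each point (warm-started from the
neighboring optimum and from the global estimate), and the grid extended
adaptively — up to ten further decades per side — until the profile crosses
`chi2_min + 3.84` (the 95% chi-squared threshold for one degree of freedom)
or hits the parameter bound. Interval endpoints are interpolated linearly
on the square-root scale `sqrt(chi2 - chi2_min)`, which is exact for
quadratic profiles and accurate on steep ones; if a re-optimisation finds a
better optimum than the original fit, the threshold and reported estimate
are re-anchored there, so `lower <= estimate <= upper` always holds. A side
that never crosses within bounds is reported open (`NA`) — practical
unidentifiability.

When the individual parameters are unidentifiable, the (fixed beta,
re-optimised gamma) pairs harvested from the beta profile — restricted to
the data-consistent part, `chi2 <= threshold` — trace the identifiable
combination. It is fit with the rational form
`gamma = (beta + a)/(beta + b)`: for fixed `b` the optimal `a` is a linear
least-squares solve, so `b` is scanned over a wide grid excluding poles
inside the observed beta range, then the pair is polished with
`minpack.lm::nlsLM`. The scan matters: the pairs often lie on a
`beta (1 - gamma) ~ const` ridge on which a naive joint fit is
ill-conditioned. Note the rational form contains that ridge as its
`beta -> Inf` limit, with `b - a` the ridge constant.

On synthetic xenograft-scale data (plateau 2,000 mm^3, 20 time points,
8 replicates, 5% noise) the gamma point estimate is recovered with ~4%
median relative error and both 95% profile intervals cover the truth at
nominal rates, while the beta point estimate carries ~11% median error —
beta sits along the sloppiness ridge, the same practical-identifiability
phenomenon that motivates the identifiable-combination step in the first
place.

# Surfaces and regions

Per-node 95% intervals become nodes of two *confidence hypersurfaces*
(lower and upper) per SM parameter over the `(p_div, div_lim)` rectangle.
The surfaces are bilinear interpolants on the (irregular) node grid —
exact at nodes, exact for affine node data, no extrapolation — with
`div_lim` treated as continuous; the source method's extra coordinate
transformation is presentation-only and omitted from computation. A node
with an open interval is an error in the strict API (`surface_nodes`);
the pipeline's default (`bounded_ci = TRUE`) instead substitutes the edge
of the explored profile box, a conservative choice that can only widen the
bands and therefore only enlarge the inferred region. This matters at
reduced simulation horizons (e.g. 100 iterations), where the tumor has not
saturated and the vB fit runs along its Gompertz-like `gamma -> 1`
boundary at most nodes.

A surrogate value `s` is *admissible* at an ABM parameter point if it lies
between the surfaces; `admissible_region()` evaluates this on a 101 x 101
mask (resolution configurable). Per the final step, beta values are sampled
(25 by default, evenly spaced) across the data-admissible beta range, gamma
is paired through the identifiable combination, per-pair regions are
intersections of the beta- and gamma-admissible masks, and the reported
region is their union. Masks come with exact set algebra
(`region_intersect`, `region_union`), area fractions, and a membership test
used by the end-to-end closure check: data generated by the ABM at
(0.125, 12) must yield a region containing (0.125, 12).

# Morphology metrics

From final snapshots: the farthest-cell Euclidean distance from the
initial tumor centroid; the box-counting dimension of occupied vasculature
sites (dyadic box sizes from 1 lattice unit up to a quarter of the occupied
bounding box, least-squares slope of `-log N(eps)` vs `log eps`); the
surface area and volume of the enclosing surface of the tumor after
removing 26-connected components below 50 voxels (migrated satellites); and
compactness. Two deliberate choices:

* **Enclosing surface.** The enclosing shape is the convex hull of the
  filtered voxels' corner points, computed by an internal quickhull
  (coplanar lattice points are absorbed into faces rather than jittered).
  An alpha-shape would follow concavities more closely; the convex hull is
  the stricter, dependency-free variant of the same "surface that encloses
  all points" intent, and shared by both parameter sets being compared.
  Voxel corners (rather than centers) make a solid block recover its
  physical dimensions exactly.
* **Compactness.** The literal typeset formula
  `Vol^(1/3) (36 pi)^(1/6) / SA` is not dimensionless and cannot equal 1
  for a sphere; the dimensionally corrected sphericity
  `(36 pi)^(1/6) Vol^(1/3) / sqrt(SA)` is used (the literal variant stays
  available behind a flag). It is scale-invariant, exactly 1 for spheres,
  and `(36 pi)^(1/6)/sqrt(6) = 0.898` for cubes.

Replicate comparisons between parameter sets use Welch's two-sample t test.

# Synthetic data

`generate_growth_data()` emulates a xenograft volume study: a von
Bertalanffy ground truth with `gamma = 2/3`, `beta = 0.15`/day and plateau
`(alpha/beta)^(1/(1-gamma)) = 2000` mm^3 from 100 mm^3, measured every
3 days with 8 replicate animals and multiplicative lognormal noise
(5% CV) — volumes are positive and caliper error scales with size. The
reported `sigma_i` is a pooled-CV standard error
(`cv_pooled x z_i / sqrt(reps)`): per-point sample SEs from 8 replicates
carry ~25% noise and are correlated with the mean under lognormal noise,
and weighting by them measurably distorts chi-squared confidence regions
(coverage drops from ~95% to ~70% in the package's own experiments);
pooling across time points is exactly right for the constant-CV noise the
generator produces. ABM-side datasets keep raw per-point SEs, since count
noise there is not constant-CV.

What the generator does *not* emulate: measurement-schedule irregularities,
animal dropout, between-animal growth-rate heterogeneity (noise is
independent across time points rather than per-animal), or any treatment
effect. Passing tests therefore validate the machinery under a known,
well-behaved noise model, not robustness to real xenograft messiness —
real data can be swapped in through the same `time,z,sigma` CSV schema.

# Problem sizes and numerical choices

The test suite runs the ABM invariant checks at 50 iterations, the
monotonicity and metric checks at 40-60 iterations, and the end-to-end
closure at 100 iterations with 3 replicates per node; the fractal-dimension
comparison runs the full 300-iteration baseline with 3 replicates per
parameter set, and the acceptance script recomputes exactly that quantity.
Parameter-recovery protocols use 50 seeds. ODE tolerances are rtol 1e-8
with atol 1e-16 (trajectories span many orders of magnitude, so accuracy
is effectively relative); surface interpolation is exact at nodes to
1e-12; RNG streams
derive replicate seeds as `root + r`, so every result is bit-reproducible
from one root seed.

# Known limitations

* Only the 2-D ABM parameter plane `(p_div, div_lim)` is mapped; the API
  reserves vector forms but higher-dimensional hypersurfaces are not
  implemented.
* The vB surrogate degenerates toward its `gamma -> 1` (Gompertz-like)
  boundary on non-saturating data; bounded-box profile clamping keeps the
  pipeline conservative there, but region inference is correspondingly
  loose at short horizons.
* No vessel pruning, flow mechanics, or VEGF transport; oxygen is a binary
  distance threshold.
* The set-valued region construction carries no probability weighting
  across the sampled combination points.
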