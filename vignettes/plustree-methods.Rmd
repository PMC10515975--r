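---
title: "Methods: screening plus trees from TLS point clouds and SSR genotypes"
author: "plustree"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`plustree` implements a complete screening workflow for plantations whose
seed-source information has been lost: measure every tree's growth
structural characteristics from terrestrial laser scanning (TLS) point
clouds, group the trees genetically from co-dominant SSR markers, and pick
the best-growing trees *within* each genetic group so that the selected set
keeps both phenotypic superiority and genetic diversity. This vignette
documents the models, the operational definitions, the tunable parameters,
and the choices made where the design was genuinely open.

## The synthetic stand: what it emulates and what it does not

Real plot scans of this kind are rarely archived, so the package ships a
stand simulator whose every output has a closed-form target.
`stand_spec()` defaults describe a plantation plot of 23 trees on a 6 m
grid (about the stem density of a 30 m x 30 m timber plot), with
stand-average structure: tree height 7.757 m, DBH 13.233 cm, crown base
2.094 m, crown width 4.254 m. Trunks are surfaces of revolution with a
linear radius taper (default 5 %/m, anchored so the radius at exactly
1.30 m matches the nominal DBH — DBH truth is exact by construction);
crowns are ellipsoids or cones filled *volumetrically* with uniform points,
so crown-base detection and cut-and-fill volume face realistic interiors
rather than hollow shells; the ground is a smooth sinusoidal relief
(default amplitude 0.3 m, wavelength 15 m), which gives the ground filter
curvature to follow without cliffs.

Point densities are a design choice, not physics: ground 50 pts/m2, trunk
2000 pts/m2 of surface, crown 150 pts/m3. They were fixed once so that a
20-tree plot (about 300k points) runs through the whole chain in well under
a minute per stage on one core while every trait stays within its stated
recovery tolerance; real TLS scans are denser, which only helps. Features
deliberately *not* simulated: occlusion (real pipelines handle it by
multi-scan registration), scanner pose and registration error, radiometric
intensity, and leaf phenology. Passing tests on these stands therefore
demonstrates the correctness of the algorithms, not robustness to every
field artefact.

`geno_sim_spec()` draws SSR panels from the admixture model itself: per
locus a base frequency vector, per ancestral population a Dirichlet
perturbation of it (`drift_concentration`, smaller = stronger divergence),
per individual a Dirichlet ancestry row Q (`admixture_alpha`), and each
allele copy sampled ancestry-first. Defaults (14 loci, 3-12 alleles,
alpha = 0.1, drift 0.5) emulate a moderately admixed plantation panel; the
test suite uses drift 0.05 / alpha 0.05 where it needs *strongly separated*
populations. Because the simulator and the sampler share the data model,
parameter recovery is a calibration check, not a tautology — the sampler
sees only the genotypes.

## Point-cloud chain

**Ground filtering** is progressive densification: the lowest point of each
5 m cell seeds the ground set; a candidate joins when its perpendicular
distance to the local ground facet is below 0.3 m *and* the iteration angle
(distance over horizontal offset to the nearest accepted point) is below
6 degrees. The classic algorithm takes the facet from a TIN; here the facet
is the plane through the three nearest accepted ground points, which
coincides with the TIN facet wherever those three points span the enclosing
triangle and avoids a triangulation dependency. Two safeguards matter in
practice: candidates are pre-restricted to within 1 m of the coarse seed
surface (speed), and after every pass any accepted point more than 0.1 m
above the lowest accepted point of its 0.5 m cell is demoted. Without the
second rule the circular point rings at trunk feet form near-horizontal
micro-facets and the ground class climbs the stem; the rule caps that
contamination at decimetre height, which the per-cell-mean DEM then
averages away.

**DEM/CHM**: per-cell mean of ground elevations at 0.1 m (empty cells
filled by inverse-distance over the three nearest filled cells), bilinear
interpolation between cell centres, nearest-cell extrapolation (with a
warning) outside the extent. Heights are normalized by subtraction;
`build_chm()` is the max-height raster of the normalized cloud.

**Trunk detection** clusters the 0.5-2.0 m slab (bracketing breast height)
in plan view with DBSCAN (eps 0.2 m, on 5 cm voxel representatives —
clustering the raw shell would make every trunk point a neighbour of every
other). A cluster becomes a seed when it is vertically continuous
(occupancy in at least 80 % of 0.25 m sub-bins), near-vertical (principal
axis within 15 degrees of plumb), and supported by enough raw points. The
seed base is the axis intersection with z = 0.

**Crown assignment** follows the transport-distance argument: vascular
plants minimize the path to their roots, so each point belongs to the seed
it can reach with the least path length. Non-ground points are
voxel-subsampled at 5 cm, joined into a k = 5 nearest-neighbour graph with
Euclidean weights, and labelled by multi-source Dijkstra from the seed
bases; full-resolution points inherit their voxel's label. Equal path
lengths go to the lower seed index (stable); unreachable components fall
back to the nearest seed by 3D distance with a warning. The crown-overlap
refinements used by interactive tools are out of scope, so accuracy in
deeply interlocking canopies is bounded by the shortest-path criterion
itself (the tests require 99 % on separated crowns, 90 % with crowns
2.5 m apart at 2 m radii).

## Trait operationalizations

* **H** — the 99.95th percentile of normalized height rather than the raw
  maximum, so a single stray return cannot set the treetop. On a volumetric
  crown the percentile sits a few centimetres below the geometric apex;
  the bias is well inside the 2 % recovery tolerance.
* **DBH** — points in the 1.25-1.35 m slice, DBSCAN-clustered in plan view
  (eps 0.03 m, min 10 points; the slice defends against branches and
  occlusion debris), nearest cluster to the stem axis, circle fit by Kasa
  algebraic least squares refined by Gauss-Newton. Diameter in
  centimetres.
* **HLC** — after excluding points within 1.5 x (DBH/2) of the axis, the
  height profile is binned at 0.1 m; HLC is the lower edge of the first bin
  above 0.3 m that holds at least 0.05 % of the tree's points *and* starts
  a run of three consecutive occupied bins. The run rule rejects isolated
  noise blobs below the true base. The occupancy threshold is deliberately
  small: the bottom tip of an ellipsoid crown is geometrically thin, and
  a threshold of 1 % would systematically overshoot the base by half a
  metre or more; 0.05 % keeps the estimate within one bin of truth while
  the run rule carries the robustness burden. Both knobs are arguments.
* **CW / CA** — crown points are everything at or above HLC (one split,
  reused by all three crown traits for internal consistency). CW is the
  mean of the east-west and north-south extents of the plan projection; CA
  is the area of its 2D convex hull.
* **CV** — cut-and-fill: rasterize crown points at 0.25 m, sum
  (max z − min z) x cell area over occupied cells. The estimator is
  slightly conservative at crown edges; at the default densities it sits
  2-7 % under the true envelope volume, inside the 10 % tolerance.
* **TV** — a single-pass cylinder decomposition of the woody points
  (trunk-tagged by default; `stem_only = FALSE` uses all points): build the
  5 cm voxel k-NN graph, take geodesic distances from the base points
  (lowest 20 cm, multi-source), cut into 0.5 m geodesic segments, split
  segments into connected components, and fit one cylinder per component
  (axis = principal direction, radius = median radial distance, length =
  axial extent capped at the segment length — geodesic paths wrap around
  the stem surface and would otherwise stretch segments into their
  neighbours). Radii are clamped non-increasing from the base (taper
  monotonicity). This is deliberately not a full topology-optimizing QSM:
  only the total volume enters the trait table, and on cylinders and cones
  the decomposition integrates to within a few percent.

`extract_traits()` composes the seven extractors and fails atomically,
naming every trait that could not be measured (a branchless stem, for
example, reports HLC, CW, CA and CV together).

## Biomass, summary statistics, accuracy metrics

Component biomass uses fixed ln-linear allometric models
(`ln W = a + b ln DBH + c ln H`) fitted destructively for plantation ginkgo
elsewhere; coefficients are constants of the method and are not refit.
Units are strict: DBH in cm, H in m, W in kg (with those units the
stand-average tree yields a plausible ~34 kg trunk biomass). Descriptive
statistics use the sample SD (n−1) and CV% = SD/mean x 100. The accuracy
triple for LiDAR-vs-field comparison is computed exactly as conventionally
printed: `adj_r2` = 1 − SSres/SStot (the name notwithstanding, no
degrees-of-freedom adjustment — the output carries an `adj_r2_paper` alias
to make that explicit), RMSE, and rRMSE = RMSE/mean x 100. Trait
correlations use Spearman's rank method with average ranks.

## SSR statistics and the admixture model

Genotypes are co-dominant: an unordered pair of allele labels per
individual and locus, missing as NA (the package also reads STRUCTURE
two-row files and GenAlEx-like two-column CSV). Per locus:
Na = observed alleles; Ne = 1/sum p^2; Ho = fraction heterozygous;
He = 1 − sum p^2 (optional n/(n−1) small-sample correction);
I = −sum p ln p; PIC = 1 − sum p^2 − sum_{i<j} 2 p_i^2 p_j^2; and a
Hardy-Weinberg chi-square over genotype classes with df = G − Na,
G = Na(Na+1)/2 (skipped for monomorphic loci). Frequencies use per-locus
non-missing denominators. Nei's standard distance between individuals
represents each individual by per-locus frequency vectors (1 / 0.5 / 0)
and caps infinite distances (no shared alleles anywhere) at a configurable
maximum; a shared-allele distance is available as an alternative.
Neighbour-joining trees come from the standard agglomeration; negative
branch lengths are clamped to zero with the clamped amount moved to the
sister branch, preserving cherry path lengths.

The admixture model is fitted by a single-chain Gibbs sampler with
conjugate updates: latent per-copy ancestry given (Q, P); P rows from
Dirichlet(1 + counts); Q rows from Dirichlet(1/K + counts). K = 1 is
closed-form. The reference implementation of this model runs hundreds of
thousands of sweeps; here the defaults are 2000 sweeps with 500 burn-in,
which on desk-scale panels (tens of individuals, ~14 loci) reproduces
strongly separated structure to within a mean absolute Q error well under
0.1. Full-length runs remain a parameter choice. Model choice uses the
Evanno statistic dK(K) = mean_runs |L(K+1) − 2L(K) + L(K−1)| / sd_runs L(K)
on a contiguous K range; because the denominator is a run-to-run sd, at
least five runs per K are needed for a stable peak — with two runs a
freakishly small sd at some K can misplace the argmax, which is why the
scan default is five runs. Components are identified only up to
relabelling; `align_q()` greedily matches columns before any comparison
(the CLUMPP role), and a stacked-bar export stands in for dedicated
plotting tools. Group assignment is argmax of the Q row (ties to the lower
index, flagged) or, alternatively, cutting the NJ tree into k components by
removing its k−1 longest edges; both routes are exposed so their agreement
can be quantified.

## Within-group evaluation and selection

Traits are z-scored within each genetic group (sample SD; a configurable
population-SD convention exists), constant traits are dropped per group
with a warning, and groups smaller than two pass through flagged. PCA is
the eigendecomposition of the correlation matrix: loadings (eigenvector x
sqrt(eigenvalue)) are trait-component correlations bounded by 1, the
contribution rate of component j is 100 lambda_j / p, and the smallest m
whose cumulative contribution reaches 85 % is retained. Eigenvector signs
are fixed so each component's largest-magnitude loading is positive,
removing solver ambiguity. Scores use unit-norm eigenvector coefficients
by default; published score scales differ between statistical packages
(some print scores in the hundreds), so the coefficient convention is an
argument and is recorded on the output, and the composite-score operation
F = sum_n w_n F_n is defined independently of any scale, with the retained
contribution rates (as fractions) for weights. Selection ranks F
descending within group and keeps max(1, ceiling(0.10 x n_group)) trees —
the ceiling with a floor of one, so a three-tree group still contributes
one representative; ties break by tree id, stably.

## Numerical choices and degenerate inputs

Neighbour searches use a uniform-grid bucket index with progressive ring
expansion (exact, with brute-force fallback); bucket sizes at hot call
sites are tied to the voxel pitch because crown-clustered densities defeat
a global uniform-density estimate. Degenerate cases are first-class: empty
clouds, x-y-collinear scenes and all-missing loci raise errors; monomorphic
loci skip the HWE test; zero-variance measured vectors flag `adj_r2` as
undefined; a flat dK profile reports "no peak" rather than an arbitrary K;
pairs of individuals sharing no alleles are capped, not infinite. All
stochastic stages (simulators, sampler, pipeline) are deterministic given
their seed, and seeds derived for scan runs stay within 32-bit range.

## Problem sizes

The shipped tests run the full point-cloud chain on a 20-tree plot
(~300k points, about 40 s end to end), dK model choice on ten replicated
K = 3 panels (n = 60, L = 14, five 300-sweep runs per K), and the complete
pipeline on a six-tree plot. These sizes were chosen once as the smallest
stands and panels on which every stated recovery tolerance is testable
with margin.

## Known limitations

No binary LAS/LAZ reader (XYZ/ASCII-PLY only); no occlusion or
registration-error simulation; the shortest-path criterion without
crown-overlap refinement bounds accuracy in heavily interlocked canopies;
the QSM is volume-oriented, not an architectural model; allometric
coefficients are external constants; and the admixture sampler is a single
chain — run-to-run spread enters only through the dK scan, not within-run
convergence diagnostics.
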