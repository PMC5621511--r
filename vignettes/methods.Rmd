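---
title: "Methods: richness hotspots, nestedness nulls, constraint envelopes and DEC biogeography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: richness hotspots, nestedness nulls, constraint envelopes and DEC biogeography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macrorich)
```

`macrorich` chains the four analyses that together explain a gridded
species-richness pattern: probabilistic hotspot delineation, nestedness and
co-occurrence null-model tests, richness–environment regression with
constraint envelopes, and likelihood-based historical biogeography. This
vignette describes each model, its assumptions, the tunable parameters, and
the numerical choices made where the design was genuinely open. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The synthetic world

All downstream stages are exercised on synthetic data with the statistical
structure the analyses assume, generated by three functions.

**`make_environment()`** builds co-registered environmental surfaces on a
regular grid around a single energy peak. PET (mm/yr) decays as a Gaussian
kernel of scale `decay` (in cells) from the peak, from 1800 mm/yr at the
peak to a 600 mm/yr baseline; AET tracks the same kernel (400–1500 mm/yr);
temperature seasonality (%) increases away from the peak (2–12%); altitude
is unstructured noise around 400 m. Independent Gaussian noise with standard
deviation `noise_sd` times each layer's deterministic range (default 0.05)
is added per cell. These magnitudes are ballpark Neotropical lowland values;
only their ordering and co-gradient structure matter to the analyses.

**`make_ranges()`** emulates a source–sink range structure. Each species'
seed cell is drawn with probability proportional to normalized energy raised
to `placement_strength` (default 6, concentrating origins near the peak),
and the range grows into a single rook-connected patch by always accreting
the highest-energy frontier cell. Range sizes are lognormal with median 12%
of the grid and `sdlog = 0.9` — a heavy-tailed size distribution with a few
near-ubiquitous species and many small ones, as in real range-size
distributions. Overlaying such ranges produces (i) a spatially clustered
richness peak at the energy maximum, (ii) assemblages away from the peak
that are nested subsets of richer ones, and (iii) strong positive
co-occurrence. The defaults used throughout the tests are a 20×20 grid (400
cells) and 50 species: large enough that the hotspot, nestedness and
co-occurrence signals are unambiguous, small enough that hundreds of seeded
replicates run in minutes.

What the generator does **not** emulate: real range-shape irregularity,
river or topographic barriers, spatial autocorrelation in the noise, or
mid-domain artefacts. Passing tests therefore demonstrate the correctness
and calibration of the statistics, not their behaviour under every real-data
pathology.

**`simulate_dec()`** runs the dispersal–extinction–cladogenesis process
forward along a dated tree from a known root range: per-area gains compete
as exponentials at rate `d` times the number of occupied source areas,
per-area losses at rate `e`; at each node a cladogenetic event is drawn from
the DEC set (below). The full event log is returned, and
`replay_history()` reproduces the tip ranges from it exactly — the
invariant that guarantees the log is complete. A lineage whose range becomes
empty terminates the replicate, which is resampled (capped at 100 attempts)
— the standard conditioning-on-survival convention for range-evolution
simulators.

## Hotspot delineation

Global structure is tested with Moran's *I* (expectation $-1/(n-1)$ under no
autocorrelation), with inference either from the Cliff–Ord normality
variance or by seeded permutation (999 draws by default). Local structure
uses the self-inclusive Getis–Ord statistic

$$Z_i = \frac{\sum_j w_{ij} x_j - \bar X \sum_j w_{ij}}
{S\sqrt{\left[n\sum_j w_{ij}^2 - (\sum_j w_{ij})^2\right]/(n-1)}},$$

with $\bar X$ and $S$ the global mean and population standard deviation.
Cells with corrected-significant $Z>0$ are grouped into queen-connected
clusters; significant $Z<0$ cells (coldspots) are labelled separately.

Choices: binary queen contiguity with self-inclusion is the default weight
scheme (the common default of GIS hotspot tools, which rarely document it);
multiple testing uses Benjamini–Hochberg FDR at $\alpha = 0.05$ with a
`correction = "none"` option since raw thresholds are also common practice.
Cells with no neighbours are excluded from inference. Because cell-level
$Z$ scores do not aggregate canonically to a cluster-level score, the
cluster summary reports both the maximum and the mean $Z$ per cluster and
leaves the choice to the user.

## Nestedness

Three indices are implemented, all permutation-invariant to the input
row/column order:

* **NODF** — mean paired overlap over all row pairs and column pairs with
  strictly decreasing marginal totals (pairs with equal totals contribute
  0); decomposes into row (`NODFr`, incidence) and column (`NODFc`,
  composition) components. Range 0–100, larger = more nested. Lines with
  zero total contribute 0, which keeps the index defined on null replicates
  whose column sums may reach zero.
* **Matrix temperature (T)** — the matrix is packed (rows and columns by
  decreasing totals; ties resolved canonically by bipartite
  colour-refinement keys plus content passes, so the index does not depend
  on the input order), cells are mapped to the unit square, and the fill
  isocline is the symmetric power curve $(1-u)^p + (1-v)^p = 1$ with $p$
  solved so the area inside the curve equals the fill ($p = 1$ gives the
  straight diagonal at 50% fill). Unexpected presences (outside the curve)
  and absences (inside it) score the squared distance to the isocline along
  the cell's (1,1) diagonal, normalized by that diagonal's in-square length.
  The mean unexpectedness is rescaled by the maximum attainable for the same
  shape and fill, so $T \in [0, 100]$ with 0 = perfectly nested. The
  temperature literature spans several isocline conventions and no published
  formula is canonical; this package pins the curve family, the distance
  geometry and the normalization explicitly (and the test suite carries an
  independent cell-enumeration oracle for it). One consequence worth noting:
  because the matrix is repacked internally, the complement of a nested
  staircase is itself perfectly nested after packing — anti-nested behaviour
  is exhibited by checkerboards, not complements.
* **Discrepancy (BR)** — after ordering columns by decreasing totals, the
  number of presences outside each row's leftmost $r_i$ slots: the minimum
  number of shifts to the maximally packed matrix with the same row sums.

Significance uses the **fixed-rows / equiprobable-columns** null: each
replicate keeps every species' occurrence count and places its presences
uniformly at random across sites. `nestedness_test()` reports the observed
index, the null mean and percentile 95% CI over `n_iter` replicates (10,000
by default), and the one-tailed Monte-Carlo $p$ in the nested direction
(smaller-is-nested for T and BR, larger for NODF) with the $+1$ correction.
The opposite tail is always reported too, and a result whose significant
tail opposes the nested direction is flagged as a direction conflict rather
than silently resolved — real datasets do occasionally produce such
conflicts between indices. The energy-ordered analysis is `pack(...,
external_site_scores = )` followed by the same indices; since all three
indices are order-invariant, the external ordering affects display, not
inference, and the null model is unchanged.

The exported `pack()` breaks total-ties by original index (stable,
reproducible for display). The internal packing used by T and BR instead
resolves ties canonically: when one margin's totals are tie-free it anchors
the other margin's content sort; otherwise rows are first keyed by
bipartite colour refinement (colour = totals, iteratively recoloured by the
multiset of colours a line intersects — invariant to input order by
construction) before alternating content sorts. The test suite checks that
T and BR are bit-identical across random row/column permutations, including
fully tied checkerboard and block structures.

## Co-occurrence

The C-score is the mean number of checkerboard units
$CU_{ij} = (r_i - S_{ij})(r_j - S_{ij})$ over species pairs.
`cooccurrence_test()` compares it against the same
fixed-rows/equiprobable-columns null (50,000 replicates by default) and
reports the standardized effect size $\mathrm{SES} = (\mathrm{obs} -
\bar{\mathrm{null}})/\mathrm{sd}(\mathrm{null})$ plus both Monte-Carlo
tails. Negative SES means more co-occurrence (aggregation) than expected;
with approximately normal deviations about 95% of SES values fall in
$[-2, 2]$ under the null — a coverage the acceptance script recomputes.
The null variance is reported in population form (divisor $n$); at tens of
thousands of replicates the distinction from the sample variance is
negligible, but the convention is pinned. Species occupying every site
contribute $CU = 0$ pairs and are retained.

## Richness–environment models

* `pearson()` is the product-moment correlation with the usual *t*-based
  two-tailed $p$.
* `forward_stepwise()` adds, at each step, the candidate with the largest
  AICc decrease and stops when none decreases it. AICc uses the
  small-sample correction $\mathrm{AICc} = \mathrm{AIC} + 2k(k+1)/(n-k-1)$
  with $k$ counting the intercept and the error variance. Ties are broken
  by candidate order, making selection deterministic. Selected terms are
  reported ordered by absolute standardized coefficient.
* `sar_fit()` fits the spatial-error model $y = X\beta + u$,
  $u = \lambda W u + \varepsilon$ by profile maximum likelihood over
  $\lambda$. The log-determinant uses the spectrum of the row-standardized
  contiguity matrix, which is real because $W$ is similar to the symmetric
  $D^{-1/2}BD^{-1/2}$. The error form (rather than the lag form) is the
  usual recommendation for gridded richness, where autocorrelation is a
  nuisance rather than a substantive diffusion process; a lag variant is
  available behind `variant = "lag"`. The reported $R^2$ is the squared
  Pearson correlation of the trend ($X\hat\beta$) with the observations — a
  pseudo-$R^2$, labelled as such; `lambda_se` comes from the curvature of
  the profile log-likelihood.
* `quantile_envelope()` characterizes constraint envelopes with linear
  quantile fits at $\tau = 0.01$ and $0.99$. The fit profiles the intercept
  (for fixed slope the optimal intercept is a type-1 $\tau$-quantile of the
  residuals) and minimizes the resulting convex one-dimensional check loss
  by Brent search — exact enough that points on an exact line recover the
  slope to $10^{-6}$. Slope-zero inference is a seeded permutation
  rank-score test: under the null the scores $\tau - \mathbf 1[y < q_\tau]$
  are exchangeable against $x$, and $\sum (x_i - \bar x)\,\psi_i$ is
  re-drawn over `n_boot` permutations (10,000 by default). With fewer than
  30 observations the extreme-quantile fits are unstable and the function
  warns.

## Historical biogeography

`dec_loglik()` implements DEC pruning over the state space of all non-empty
area subsets up to `max_range_size` (default: all areas, matching an
unconstrained four-area analysis), plus the absorbing empty range.
Anagenetic transitions use the exponential of the generator with per-area
gains at rate $d$ (times the all-ones dispersal multiplier by default) and
losses at rate $e$; transition matrices come from one eigendecomposition of
the generator per evaluation (with a `Matrix::expm` fallback whenever the
eigensystem fails to reconstruct the generator to $10^{-9}$). At each node
the allowed cladogenetic events — sympatric copying for single-area ranges;
subset sympatry and single-area vicariance for widespread ranges — receive
equal probability. Under DEC+j, founder-event jumps (one daughter keeps the
ancestral range, the other jumps to a single outside area) take total
weight $j$ split equally among jump pairs, and the remaining $1-j$ is split
among the non-jump events; at $j = 0$ the likelihood collapses to plain DEC
to $10^{-10}$, which the tests assert. The root prior is uniform over the
allowed non-empty ranges (a fixed root range can be supplied instead); this
is a documented divergence from tools that weight root states by the
cladogenesis normalization. `fit_dec()` maximizes by bounded L-BFGS-B and
reports $\mathrm{AIC} = 2\,\mathrm{df} - 2\ln L$ (df = 2 or 3);
`compare_models()` ranks by AIC and flags $\Delta\mathrm{AIC} < 2$ as
indistinguishable rather than declaring a winner.

`bsm()` draws full histories conditional on the tips and the fitted
parameters: the root state from prior × conditional likelihood, daughter
pairs at each node from the cladogenesis table weighted by the branch-top
likelihoods, branch endpoints from $P(t)$ × subtree likelihood, and branch
paths by exact endpoint-conditioned uniformization (no time-discretization
bias). An anagenetic gain of area $k$ by range $R$ adds $1/|R|$ to each
source-area row of the source×destination dispersal matrix — the coding
deliberately never hard-codes area names, taking the area list from the
coding table. Because the event taxonomy a counter should use is a genuine
judgment call, anagenetic dispersal and cladogenetic jumps are accumulated
in separate matrices and per-event-type totals are reported. The tests
verify the conditional machinery against the forward simulator through the
tower identity $E_{\text{forward}}[\text{counts}] =
E_{\text{tips}}[E_{\text{BSM}}[\text{counts} \mid \text{tips}]]$, which
holds when BSM runs at the true parameters with the root fixed at the
simulation's root range.

## Grid assembly and map comparison

Richness is the per-cell count of overlapping ranges; the presence–absence
matrix keeps only sites with records (so no all-zero columns). Regridding
aggregates per-species occupancy by any-presence within each coarse cell
and recomputes richness — never by summing fine-cell richness, which would
count a species once per fine cell. Cohen's kappa compares two richness
maps after binning both into `n_classes` equal-width classes (10 by
default) over their joint range on the jointly valid cells; the class-based
comparison convention is standard in map-comparison software but the
binning is rarely documented, so it is pinned here. Grid convention
throughout: origin at the north-west corner, row-major, 0-based cell
addressing in files.

## Numerical and degenerate-input choices

* Constant surfaces make Moran's I and Gi* undefined — both error rather
  than return 0.
* `kappa_compare()` of two constant maps returns 1 if they agree and 0
  otherwise (observed agreement at that degenerate marginal table).
* Temperature is undefined at 0% or 100% fill (error); the isocline
  exponent is solved to $10^{-12}$ and per-cell crossings by interpolation
  plus Newton polish to ~$10^{-14}$.
* Monte-Carlo $p$-values always use the $(k+1)/(n+1)$ correction, so
  $p = 0$ is impossible.
* All stochastic functions take explicit seeds, save and restore the
  caller's RNG state, and are bit-reproducible; the pipeline validates that
  every stochastic stage carries a seed before any computation runs.

## Problem sizes used by the test suite

The suite exercises the calibration claims at: 500 null-drawn matrices ×
1,000 null replicates for SES coverage; 400 calibration runs × 1,000
replicates for nestedness test size (asserted at 5% ± 2.5 percentage
points, ≈2.3 binomial standard errors); 100 seeded end-to-end worlds (99
nulls per index, sufficient for the minimum attainable $p = 0.01$); 100
50-tip DEC recovery replicates; and a 20-tip forward-vs-BSM comparison
with 400 forward simulations against 60 tip-sets × 25 maps. These sizes
were chosen once as the smallest at which the Monte-Carlo bands are
meaningful.

## Known limitations

* Weights are first-order contiguity only (no distance bands or kernels).
* The SAR profile assumes the weight matrix derives from symmetric binary
  contiguity (true of `build_weights()` output).
* Quantile fits are strictly linear in one covariate; no crossing
  constraint is imposed beyond what the data induce.
* DEC is unstratified (no epoch-specific dispersal multipliers) and the
  state space grows as $2^{|areas|}$; intended for small area sets.
* The temperature index follows this package's pinned formulation; values
  are comparable within the package, not bit-identical to legacy binaries.
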