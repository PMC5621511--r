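# macrorich

Why is species richness concentrated where it is? For clades like the
Neotropical primates, a gridded richness map typically shows one dominant
high-richness region, assemblages elsewhere that look like subsets of it,
and strong covariation with environmental energy. `macrorich` is an R
package for making each link of that argument quantitative and testable:

1. **Hotspot delineation** — is the richness peak a statistically
   delimited cluster, not an arbitrary cut-off? Global Moran's *I*
   ($E[I] = -1/(n-1)$ under no autocorrelation) plus the local Getis–Ord
   statistic
   $Z_i = (\sum_j w_{ij} x_j - \bar X \sum_j w_{ij}) /
   (S\sqrt{[n\sum_j w_{ij}^2 - (\sum_j w_{ij})^2]/(n-1)})$,
   with FDR-corrected significant cells grouped into contiguous clusters.
2. **Nestedness** — are poor assemblages subsets of rich ones? Matrix
   temperature (T), Brualdi–Sanderson discrepancy (BR) and NODF, tested
   against a fixed-rows / equiprobable-columns Monte-Carlo null.
3. **Co-occurrence** — do species aggregate or segregate? The checkerboard
   C-score, $CU_{ij} = (r_i - S_{ij})(r_j - S_{ij})$ averaged over species
   pairs, with standardized effect size
   $\mathrm{SES} = (\mathrm{obs} - \mu_{null})/\sigma_{null}$ against the
   same null.
4. **Environment** — which covariates carry the pattern, and where are the
   constraints? Pearson correlations, forward-stepwise OLS under AICc, a
   spatial-error SAR model ($y = X\beta + u$, $u = \lambda Wu +
   \varepsilon$) fitted by profile ML, and 1st/99th-percentile
   quantile-regression envelopes with permutation rank-score inference.
5. **History** — where did the clade originate and how did it spread?
   DEC and DEC+j range-evolution likelihoods on a dated tree, AIC model
   comparison, and biogeographic stochastic mapping with per-area-pair
   dispersal counts.

A first-class synthetic-data module (`make_environment()`, `make_ranges()`,
`simulate_dec()`) generates energy gradients, source–sink range sets and
known DEC histories, so the whole chain is testable without external GIS or
phylogenetic data.

## Worked example

```r
library(macrorich)

env    <- make_environment(shape = c(20, 20), peak = c(10, 10), decay = 5,
                           noise_sd = 0.05, seed = 2)
ranges <- make_ranges(50, env, seed = 1002)
grid   <- stack_richness(ranges)
grid
#> <richness_grid> 20x20 cells of 1 deg; 303 occupied cells; max richness 50

vals <- grid$richness[grid$valid]
morans_i(vals, build_weights(grid))$I
#> [1] 0.9233767

Wg <- build_weights(grid, include_self = TRUE)
delineate_hotspots(getis_ord_gstar(vals, Wg), Wg)
#> <hotspot_result> 1 hotspot cluster(s), 47 hot cells; 0 coldspot cluster(s) (alpha=0.05, fdr)

M <- build_matrix(ranges)
nestedness_test(M, "T", n_iter = 200, seed = 2)
#> <nestedness_result> T obs=0.9326 null=15.22 (CI 14.69-15.7) p=0.004975 (less)

cooccurrence_test(M, n_null = 200, seed = 6)$ses
#> [1] -185.9313
```

Read: richness is strongly autocorrelated (I = 0.92); exactly one
significant Gi* cluster of 47 cells sits on the energy peak; the matrix is
far colder (more nested, T = 0.93) than its null expectation (15.2); and
the SES far below −2 means species co-occur massively more than chance —
the aggregation a source–sink world produces.

The historical module works the same way from a tree plus a tip coding:

```r
tree   <- read_tree(system.file("extdata", "demo-tree.nwk", package = "macrorich"))
coding <- read_coding(system.file("extdata", "demo-coding.csv", package = "macrorich"),
                      tree = tree)
fits <- list(fit_dec(tree, coding, "DEC"), fit_dec(tree, coding, "DEC+j"))
compare_models(fits)          # AIC table with delta-AIC and near-tie flags
bsm(tree, coding, fits[[1]], n_maps = 1000, seed = 1)  # dispersal counts
```

(The packaged tree and coding are synthetic, generated by
`simulate_dec()`.)

`run_pipeline()` chains every stage from a YAML/list config with per-stage
seeds, writing per-stage CSV/JSON outputs, a log, and a manifest with
content hashes; see `inst/extdata/demo-config.yaml`.

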