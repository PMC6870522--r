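# ncmtools

Neutral community assembly analysis for microbiome OTU tables.

`ncmtools` is for ecologists asking whether a host-associated microbial
community is shaped by host selection or assembled passively by dispersal
and drift. It re-implements, as a tested and reusable R pipeline, the
community-assembly analysis applied to wild insect gut microbiomes:
OTU-table IO and filtering, diversity and permutation statistics, and —
at its core — the Sloan neutral community model, which classifies every
OTU as neutrally distributed or under positive/negative host selection.
A synthetic-data module generates count tables with the exact statistical
structure the model assumes, so the whole pipeline is testable without
any external data.

## The model

Each host individual is a local community of size `N` assembled from a
metacommunity. Under neutrality with migration rate `m`, a taxon with
metacommunity relative abundance `p` has local abundance

    x ~ Beta(N m p, N m (1 - p))

and is detected when `x` exceeds the detection limit `d = 1/N` (one
read), so its expected occupancy across hosts is
`f(p) = 1 - pbeta(d, N m p, N m (1 - p))`. The package estimates `m` by
bounded nonlinear least squares of observed against predicted occupancy,
builds a confidence band around the fitted curve, classifies each OTU
(above = positive selection, inside = neutral, below = negative
selection), and compares the neutral fit against a binomial subsampling
null by generalized R² and AIC.

## Worked example

Simulate a pure-neutral survey (25 hosts, 200 OTUs, `m = 0.1`), fit the
model, and classify OTUs:

```r
library(ncmtools)

cfg <- simulation_config(n_taxa = 200, n_samples = 25, m = 0.1,
                         N_local = 30000, depth_range = c(30000, 30000),
                         seed = 7)
p   <- sample_metacommunity(cfg)
tab <- simulate_neutral_table(p, cfg$m, cfg$N_local, cfg$n_samples,
                              depths = 30000, seed = 8)
tab
#> count_table: 25 samples x 200 OTUs, 746,715 reads

su  <- prepare_metacommunity(tab)
fit <- fit_neutral(su)
fit
#> Sloan neutral model: m = 0.1152 (SE 0.0043), R2 = 0.909, AIC = -1274.2
#> binomial null:       R2 = 0.304, AIC = -870.1

round(classify_otus(su, fit, level = 95)$fractions, 3)
#> neutral   above   below
#>   0.715   0.280   0.005
```

Reading the numbers: the fitted migration rate (0.115) sits close to the
generating 0.1 (the +15% is the documented in-sample estimation bias, not
noise); the neutral model beats the binomial null decisively (ΔAIC ≈ 404);
and 71.5% of OTUs are classified neutral at the 95% level *even though
every OTU here is neutral by construction* — the Wilson band of the
published procedure flags ~30% of neutral OTUs, mostly abundant taxa
observed in every host. That is why the package also provides the
calibrated `classify_otus(..., method = "prediction")` band (<1%
non-neutral on the same data), and why neutral fractions from real surveys
should be compared against this simulated null rather than read as
calibrated percentages.

Downstream, the same table feeds `distance_matrix()`, `permanova()`,
`cap_discrim()`, `shared_otu_counts()`, `aggregate_taxonomy()` and the
per-location fits of `fit_per_group()`; `run_pipeline()` orchestrates all
stages from two input files, and `inst/cli/ncmtools-cli.R` exposes every
stage as a command-line subcommand (`filter`, `diversity`, `permanova`,
`cap`, `neutral-fit`, `simulate`, `pipeline`).

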