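---
title: "Neutral community assembly analysis with ncmtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neutral community assembly analysis with ncmtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncmtools)
```

## The question the package answers

Host-associated microbial communities can be shaped by host-imposed
selection, or assembled passively by dispersal and ecological drift from a
shared regional pool. `ncmtools` implements the occurrence–abundance test
of that distinction for amplicon OTU tables: each host individual's
community is treated as a *local community* of size $N$ assembled from a
*metacommunity* (the pool across all hosts at a site), and the fraction of
taxa whose occupancy is explained by neutral dynamics is estimated.

## The model

Under neutral assembly with migration rate $m$ — the probability that a
death in the local community is replaced by an immigrant from the
metacommunity rather than by local reproduction — the stationary
distribution of a taxon's local relative abundance $x$ given its
metacommunity abundance $p$ is

$$x \sim \mathrm{Beta}\bigl(Nmp,\; Nm(1-p)\bigr).$$

A taxon is *detected* in a host when its abundance exceeds the detection
limit $d$, so its expected occupancy across hosts is

$$\hat f(p) = 1 - I_d\bigl(Nmp,\, Nm(1-p)\bigr),$$

with $I_d$ the regularized incomplete beta function
(`predict_occurrence_neutral()`). Because community size is estimated from
sequencing reads, $N$ is the mean per-sample read total and $d = 1/N$ (one
read). `fit_neutral()` estimates $m$ by bounded least squares of observed
against predicted occupancy (optimizer `nlminb` on $m \in [10^{-6}, 1]$,
relative tolerance $10^{-8}$, at most 500 iterations, multi-start at
0.01/0.1/0.5 on failure). Fit quality is the generalized
$R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ and a Gaussian-residual
$\mathrm{AIC} = n\log(\mathrm{SSE}/n) + 2k$ with $k = 2$ for the neutral
model ($m$ plus the residual variance) and $k = 1$ for the null; only
differences in AIC are interpreted.

The null model is the *binomial subsample*: local communities are random
draws from the metacommunity with no drift and no dispersal limitation,
$\hat f_0(p) = 1 - P(X \le c),\, X \sim \mathrm{Bin}(N, p)$. Two detection
cutoffs exist in circulation: $c = \lfloor Nd \rfloor$ and $c = 0$
(detection at one read). Observed occupancy is computed as "count > 0", and
$\lfloor Nd\rfloor = 1$ at $d = 1/N$ would impose a *two*-read rule on the
null only; model comparison therefore uses the one-read form. On data
generated by the binomial null itself the one-read form fits with ~30×
smaller error, and model selection then recovers the generating model in
both directions (`compare_models()`).

Each OTU is classified against a band around its predicted occupancy
(`classify_otus()`): observed occupancy above the band is consistent with
positive host selection, below with negative selection, inside with
neutrality; boundary ties count as neutral, which is conservative toward
the neutral headline fraction.

## What the synthetic generator emulates

`simulate_neutral_table()` draws latent abundances
$x_{ij} \sim \mathrm{Beta}(Nmp_i, Nm(1-p_i))$ independently per OTU and
converts them to reads. Two read models are provided:

* **threshold** (default): $c_{ij} = \lfloor \mathrm{depth}_j \cdot x_{ij}
  \rfloor$. The reads enumerate the community, so detection happens exactly
  at $x > 1/\mathrm{depth}$ — the same assumption the fitted model makes.
  Generator and predictor then *close*: simulated occupancies fall inside
  their binomial sampling bands around $\hat f(p)$ (acceptance criterion
  1), and `fit_neutral()` given the generating metacommunity recovers $m$
  with sub-percent mean bias (criterion 2).
* **binomial**: $c_{ij} \sim \mathrm{Bin}(\mathrm{depth}_j, x_{ij})$, an
  independent read-resampling layer. One-read detection then becomes a
  *soft* threshold, the hard-threshold prediction over-states occupancy
  near the detection limit, and $m$ estimates inflate by roughly 20–35%
  under a realistic lognormal metacommunity. This variant exists for
  robustness studies; calibration claims are only valid under the
  threshold model.

Defaults state a realistic survey world: lognormal metacommunity
($\mu = 0$, $\sigma = 1.5$, a typical amplicon rank-abundance spread),
$m = 0.1$, $N = 10{,}000$, read depths uniform on $[2\times10^4,
6\times10^4]$ (a `deep` preset covers the 62,000–599,000 range reported
for deeply sequenced gut surveys), and a diet mode in which a single
host-assigned OTU carries 87.6% of the reads so that host-OTU removal
leaves the published 12.4% prey fraction. The independent cross-check of
the stationary beta itself is the discrete Moran chain
(`simulate_hubbell_process()`): death of a uniformly chosen individual,
replacement by immigration with probability $m$. Its exact stationary
concentration is $m(N-1)/(1-m)$, which converges to the $Nm$ of the beta
form as $m \to 0$; the distributional cross-check is therefore run at
small $m$, where the approximation is stated.

What a green test does **not** establish: real surveys violate the
generator's independence assumptions (taxon interactions, compositional
coupling, variable per-sample detection with heterogeneous depths), and
the generator draws OTU abundances independently rather than jointly
Dirichlet — per-sample latent proportions need not sum exactly to one
before count conversion, the same independence approximation the fitted
model makes.

## Two measured caveats of the method as practiced

These two findings are computed by the test suite and the acceptance
script; they are properties of the published procedure, reproduced
faithfully, not implementation defects.

**In-sample metacommunity estimation biases $\hat m$ upward.** The
workflow estimates $p$ from the same samples whose occupancy is being
explained. Rare OTUs near the detection limit are only included when they
happened to be observed, and their pooled abundance is then conditionally
inflated (errors-in-variables plus selection). At 300 OTUs × 30 samples,
depth 50,000, $m = 0.1$, the full pipeline averages $\hat m \approx 0.12$
(+20%), and the bias decays only like $1/\sqrt{n}$ (still ~+16% at 200
samples). With the generating metacommunity supplied, the same fits are
unbiased. The acceptance report carries both numbers
(`criterion_2_recovery_rate` vs `criterion_2_full_pipeline_mean_m`).

**The Wilson band is not a calibrated acceptance region.** The published
procedure classifies an OTU against a Wilson score interval computed *at
the predicted occupancy* with $n$ = number of hosts. That is a confidence
interval for an estimated proportion, used as if it were a prediction
interval for the observed occupancy. For OTUs predicted near occupancy 1
over few hosts the two differ badly: at $\hat f = 0.99$ and $n = 30$,
observed occupancy exactly 1 has probability $0.99^{30} \approx 0.74$ yet
lies *above* the Wilson upper bound, so abundant, perfectly neutral taxa
are flagged as positively selected. On pure-neutral simulations ~32% of
OTUs are classified non-neutral at the 95% level (the deliberately failing
acceptance criterion 3). The calibrated alternative —
`classify_otus(..., method = "prediction")`, a binomial prediction band
$[\,q_{0.025},\, q_{0.975}\,](n, \hat f)/n$ — classifies <1% of the same
OTUs non-neutral. The Wilson band stays the default because it is the
published method and reproduces published headline fractions; any
biological reading of "percent neutral" should be made relative to a
simulated null (which this package provides), not to nominal CI coverage.
Notably, a ~30% non-neutral fraction on pure-neutral data is of the same
order as the non-neutral fractions typically reported for real surveys at
comparable sample sizes.

## Other design choices

* **Filters.** "At least 20 reads per OTU per sample" is implemented as
  OTU-level retention (≥ 20 reads in ≥ 1 sample), consistent with the
  other two OTU-level filters and with published community sizes; a
  cell-zeroing variant sits behind `zero_cells = TRUE`. The global 0.005%
  filter is computed on pooled reads (`mean_proportion = TRUE` for the
  per-sample-mean variant). All thresholds are inclusive; relative
  abundances are recomputed after every filter.
* **Metacommunity abundance** defaults to pooled reads
  (reads-weighted); `p_method = "mean_proportion"` is the alternative
  when sources are silent on the convention.
* **Host-OTU removal** deletes one OTU table-wide (the host-assigned OTU
  with the largest total), because OTU identity is table-wide; it can
  remove genuine conspecific-predation signal, which is acknowledged, not
  remedied.
* **Near-zero-variance screening** before discriminant analysis uses the
  common feature-screening convention: drop constant columns, and columns
  with frequency ratio > 19 *and* unique fraction < 10%; both cutoffs are
  arguments.
* **PERMANOVA** uses sequential (Type-I) sums of squares on the
  Gower-centered matrix in the user's term order, free permutation of
  labels for all terms (the within-block alternative for interactions is
  out of scope), and $p = (\#\{F^* \ge F\} + 1)/(n_\mathrm{perm} + 1)$,
  which is unbiased and never zero.
* **CAP** selects the PCoA axis count by maximizing leave-one-out
  classification success over $2..(n - g - 1)$; the permutation test
  permutes labels at the chosen axis count. A fixed `max_axes` is
  available for reproducibility.
* **Taxonomic distinctness.** The selection-class diversity comparison
  uses average taxonomic distinctness $\Delta^+$ on the seven ranks with
  equal step weights (pair distance $100\,(7-s)/7$, $s$ = deepest shared
  rank), compared between classes by bootstrapping the pooled lineages at
  each class's size. The original analysis cites several indices without a
  formula; $\Delta^+$ is this package's stated choice.
* **Rarefaction** is exact multivariate-hypergeometric subsampling, never
  with-replacement; −1 SD rarefied tables are floored at zero.
* **Seeds.** Every stochastic function takes a seed and restores the
  caller's RNG stream on exit, so seeded calls compose with user
  `set.seed()`.

## Known limitations

Single-$m$ fits per metacommunity (no per-sample $N$ likelihoods, no
time-resolved dynamics, no Etienne sampling formula); free permutations
for interaction terms; no UniFrac or richness estimators; BIOM is
supported in its JSON (1.0) dialect only. Reproducing the published survey
numbers requires downloading the deposited tables
(`scripts/reproduce_deposited.R`); the offline build is validated entirely
against the synthetic world described above.
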