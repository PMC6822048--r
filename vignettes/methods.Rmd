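---
title: "Models and methods behind poolscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poolscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscape)
```

poolscape implements a landscape-genetics analysis chain for
metapopulation-structured, pool-breeding amphibians: discrete breeding
sites, diploid microsatellite genotypes, and the question of how much of
the among-site genetic structure is explained by geographic distance alone
versus landscape features — roads, rivers, developed land cover, terrain.
This vignette documents the statistical models, the numerical choices, and
the design decisions where more than one defensible option existed. It
states no empirical result beyond what the package's tests and the
acceptance script themselves compute.

## Differentiation estimators

Within-population gene diversity is estimated with Nei–Chesser small-sample
corrections. Per locus with $k$ populations, per-locus harmonic-mean sample
size $\tilde n$ (individuals typed at the locus — per locus, not a global
constant, following the convention of the R implementations this field
uses), observed heterozygosity $\hat H_O$ and within-population gene
diversity $H_{S,\mathrm{raw}}$ averaged over populations:

$$\hat H_S = \frac{\tilde n}{\tilde n - 1}\Big(H_{S,\mathrm{raw}} -
\frac{\hat H_O}{2\tilde n}\Big), \qquad
\hat H_T = H_{T,\mathrm{raw}} + \frac{\hat H_S}{k\tilde n} -
\frac{\hat H_O}{2k\tilde n},$$

with $H_{T,\mathrm{raw}}$ computed from allele frequencies averaged
*unweighted* across populations. The multilocus estimate averages
$\hat H_S$ and $\hat H_T$ across loci before the ratio
$G_{ST} = (\bar H_T - \bar H_S)/\bar H_T$ — not the average of per-locus
ratios — again matching the field's standard implementation family.
Hedrick's standardization

$$G''_{ST} = \frac{k(\hat H_T - \hat H_S)}
{(k\hat H_T - \hat H_S)(1 - \hat H_S)}$$

rescales $G_{ST}$ by its maximum attainable value given within-population
diversity, making values comparable across markers of different
heterozygosity. Pairwise matrices are recomputed on each two-site subset
with $k = 2$ rather than decomposed from the global analysis. Negative
pairwise estimates (sampling noise around zero differentiation) are
retained, not truncated: truncation would bias every downstream regression
through the IBD intercept. Note one consequence verified in the tests: the
usual dominance $G''_{ST} \ge G_{ST}$ holds whenever $\hat H_T \ge \hat
H_S$, but reverses for the retained negative estimates.

Whether the published per-site $H_E$ values this package's bundled site
table reproduces were computed with or without Nei's unbiased correction is
not documented at the source; the unbiased form $N/(N-1)\,(1-\sum p_a^2)$
($N$ gene copies) is the default here and the raw gene diversity is an
option (`he_unbiased = FALSE`); at $n \ge 10$ the two differ in the third
decimal.

## Permutation tests

All significance testing around matrices and genotype tables is by
permutation, seed-deterministic, with the add-one rule
$p = (\#\{T_{perm} \ge T_{obs}\} + 1)/(B + 1)$:

* **Hardy–Weinberg**: Monte Carlo exact test in the Guo–Thompson spirit —
  the statistic is the conditional probability of the genotype table given
  allele counts; the null re-pairs the shuffled gene pool. An exact test
  rather than chi-square because microsatellite tables are sparse.
* **Linkage disequilibrium**: genotypic (not gametic) association, because
  phase is unknown in diploid field data; G statistic of the two-locus
  genotype table, null by permuting one locus's genotypes among
  individuals.
* **Pairwise exact G**: per-locus G on the 2 × alleles genic table, null by
  permuting individuals between the two sites (keeping each individual's
  two gene copies together), per-locus p-values combined across loci by
  Fisher's method.
* **Mantel / partial Mantel**: Pearson correlation of lower-triangle
  vectors; the null permutes the row/column order of the first matrix; the
  partial statistic is the first-order partial correlation, recomputed in
  full under each permutation. One-tailed (greater), the convention of the
  ecology packages this analysis follows. Pairs with non-finite entries
  (disconnected resistance pairs) are dropped listwise per permutation.
* **MMRR**: unstandardized OLS on unfolded matrices; simultaneous row/column
  permutation of the response; two-sided pseudo-t per coefficient.

The acceptance suite calibrates all six tests under their nulls and checks
the type-I error at $\alpha = 0.05$ lands in $[0.03, 0.07]$; with 199
permutations the add-one rejection rule (9 or fewer exceedances) is exact
for continuous statistics and slightly conservative under ties.

## Isolation by distance and its spatial scaling

Differentiation is linearized as $G_{ST}/(1-G_{ST})$, the transform under
which IBD is expected linear in distance, and distances are Haversine
great-circle kilometres on a sphere of radius 6,378,137 m (the default of
the `geosphere::distm` function used for the distance matrix). Regressions
of linearized differentiation on distance are fit by OLS (linear,
quadratic, or natural-log-distance forms) over the $n(n-1)/2$ off-diagonal
pairs; 5th/95th quantile lines are fit by check-loss minimization — a
smoothed IRLS pass followed by an exact polish that enumerates candidate
lines through pairs of low-residual points (an optimal quantile line
interpolates two data points, so the polish terminates at the exact
optimum; the tests verify equality with full pair enumeration).

The **IBD scaling profile** re-estimates the OLS slope on expanding
distance-sorted subsets: the $m$ shortest pairs for
$m = 20, 21, \dots, M$, each window with its own intercept ("variable
intercept" — nothing is shared across windows). Ties in the distance sort
are broken lexicographically by site id so profiles are exactly
reproducible. Confidence intervals are percentile intervals from
case-resampling bootstrap of the pairs within each window (1,000 replicates
by default). Pair-level resampling ignores the non-independence of pairs
sharing a site; site-level block resampling would be the conservative
alternative, but pair-level is what the profile as defined uses, and the
package exposes the window step size (`step`) to thin profiles for speed
rather than changing the estimator.

The **site isolation index** is the mean of the global linear IBD fit's
residuals over all pairs involving a site — a distance-corrected measure of
how much more differentiated a site is than its geography predicts. With a
complete pairwise design the indices sum to approximately zero (an OLS
residual property the tests assert), so the index is a relative ranking,
not an absolute quantity.

The Mantel correlogram uses 20-km distance classes; following the
established bias-avoidance rule, classes are retained only while every site
still appears in at least one pair within the class upper bound, and
Benjamini–Hochberg FDR is applied across the retained classes. Class
membership is coded 0-inside/1-outside so a positive Mantel r means
within-class genetic similarity (positive spatial autocorrelation).

## Circuit-theory resistance and model selection

A resistance surface assigns each raster cell a traversal cost ≥ 1
(background 1). Single-feature surfaces set the feature's cells to a
candidate cost; the terrain-ruggedness surface is TRI + offset everywhere;
combined surfaces take the cell-wise maximum of assigned costs (linear
features thereby take precedence over land cover). TRI is the square root
of the summed squared elevation differences to the eight neighbours, edge
cells using the neighbours available.

Effective resistance treats each cell as a graph node with edges to its 8
neighbours (4-neighbourhood available as an option, since the upstream
tools' setting is not standardized): the resistor between neighbouring
cells is the mean of their costs, times $\sqrt 2$ for diagonal neighbours.
Pairwise effective resistance comes from sparse Cholesky solves of the
grounded graph Laplacian, one factorization per connected component;
disconnected pairs are reported as `Inf`, never as a large number, and are
excluded listwise (with counts) from the Mantel and model fits downstream.
The solver is validated against series/parallel resistor laws and a dense
Laplacian-pseudoinverse oracle, and spot-checked for Rayleigh monotonicity
(raising any cell's cost cannot lower any effective resistance).

Cost optimization screens 4–7 candidate costs per feature (always including
1, which reduces the surface to uniform and hence to a pure
isolation-by-distance model) by the partial Mantel $r^2$ of effective
resistance against linearized $G_{ST}$ controlling geographic distance. A
feature "beats IBD" only if its best candidate differs from 1 *and*
improves on the cost-1 $r^2$. Model selection then fits Gaussian
identity-link linear models of the unfolded response on every non-empty
subset of the winning features' resistance matrices, plus a distance-only
IBD model, ranked by
$\mathrm{AICc} = -2\log L + 2k + 2k(k+1)/(n-k-1)$ with $n$ the number of
pairs and $k$ the coefficient count plus one for the residual variance.
"Additive models" here means variables entering additively in a linear
model — no smooth terms — since the candidate models are additive variable
combinations. Two caveats are accepted deliberately: pairwise observations
are not independent, so the AICc ranks and weights are a relative
parsimony ordering rather than calibrated inference; and $n$ is the pair
count, the only sample size available without an effective-n model.

## dbRDA and covariates

The distance-based RDA embeds the pairwise $G_{ST}$ matrix by principal
coordinates through `vegan::capscale` with the Lingoes correction for
negative eigenvalues (logged whenever it fires; an offset is applied and
logged first if the matrix contains negative entries, since raw
differentiation near zero can dip below it). Latitude and longitude enter
the conditioning matrix untransformed in decimal degrees. Terms are tested
by permutation of residuals under the reduced model (the package default
for partial models) and eliminated backward one at a time — always the
largest nonsignificant p — until all remaining terms fall under
$\alpha$. Variance fractions are adjusted $R^2$ of the partial model, the
condition-only model, and the combined model. Collinear covariates are
pruned beforehand: connected components of the $|r| > 0.7$ graph, one
seeded-random representative each, with a decision log.

## The synthetic study system

The simulator exists to give every stage ground truth, and its defaults are
fixed once to emulate the study conditions this pipeline targets:

* 8 microsatellite loci, 6 initial equifrequent alleles per locus, allele
  states as repeat counts reported as fragment sizes $100 + 2\times$count;
* two-phase mutation at rate $5\times10^{-4}$ per gene per generation, 95%
  single-step, multi-step magnitudes geometric with the success probability
  solved so the total signed step variance is 12 (matching the bottleneck
  test's settings; the upstream tool's internal parameterization is not
  published, and geometric is the conventional choice);
* 10–90 demes of $N_e = 50$ diploids, 10–40 sampled per deme, 100
  generations (drift–migration balance is effectively reached at the
  simulated migration rates);
* migration $m_{ij} \propto \exp(-\lambda R_{ij})$ on an *absolute*
  resistance scale, normalized so the best-connected deme retains 0.9 of
  its genes per generation — more isolated demes exchange less. An
  alternative would normalize each row to a fixed outflow, but that forces
  every deme to exchange the same total fraction of genes however isolated
  it is: a deme cut off by a high-cost barrier would then stay genetically
  *average* rather than drifting apart, and no isolation signal could
  exist for the site-isolation index to detect. No generative model
  linking landscape to gene flow is established for this system; the
  exponential-in-resistance link is the simplest monotone choice and is
  used *only* to manufacture ground truth, not as a claim about any real
  species. $\lambda = 10$ was chosen once alongside the other demographic
  defaults so that, on a uniform default grid, simulated global $G_{ST}$
  lands near 0.02–0.05 with a clear distance trend — the regime the
  analysis chain is designed for (landscapes with strong barrier features
  sit above that, as they should). (Effective resistance between points on a uniform
  2-D grid varies only logarithmically with distance, so $\lambda$ must be
  of this order for resistance differences to shape migration; the global
  shift by the smallest between-deme resistance before exponentiation
  cancels in the normalization and avoids underflow.)
* demes are placed on habitat cells — never on roads, rivers, or developed
  cover. A deme sitting on a high-cost cell would carry a constant
  resistance offset to every partner that the row-normalized migration
  kernel cancels, decoupling the resistance matrix from the realized gene
  flow; breeding pools on riverbeds are also not a condition the field
  data contain.
* linear features are rasterized 4-connected (diagonal steps fill a corner
  cell), the raster analogue of buffering linear features for continuity:
  without it, an 8-neighbourhood path slips through the diagonal cracks of
  a one-cell line and barriers become porous.

Artifact injection adds, in order: null alleles (each gene copy converts to
a non-amplifying state with the configured probability; one null makes an
apparent homozygote, two make a missing call), random missingness, and
appended full-sib families bred by Mendelian sampling from two sampled
parents, with a truth table for the sibling filter to be checked against.

What the simulator does *not* emulate — and hence what green tests do not
demonstrate about real data: selection, sex-biased dispersal, overlapping
generations, spatial heterogeneity in deme size, allele-size homoplasy
constraints (the ladder is unbounded above 2 repeats), and genotyping error
beyond missingness and nulls. Parameter-recovery results show the chain
detects the structure its own generative model builds in; field inference
still rests on the usual landscape-genetics assumptions.

## Bottleneck testing

For each polymorphic locus at a site the observed unbiased $H_E$ is
compared with the heterozygosity expected at mutation–drift equilibrium
*conditional on the observed allele count* $k$ and sample size: coalescent
samples are simulated under the two-phase model, $\theta$ tuned by
bisection (on a log grid, with a simulation-based estimate of
$\mathbb E[k\,|\,\theta]$) until the expected allele count matches, and
replicates retained only when they carry exactly $k$ alleles —
acceptance sampling, since the exact conditioning scheme of the reference
program is not published. A capped attempt budget reports loci where the
conditioning fails rather than looping forever. The site-level test is a
one-tail Wilcoxon signed-rank across loci for heterozygosity excess. The
Monte Carlo conditioning makes this the most expensive stage; the package
default of 1,000 retained replicates per locus matches the conventional
setting, and the tests run reduced sizes (60–240) whose Monte Carlo error
they account for explicitly.

## Problem sizes and determinism

Every stochastic function takes a `seed` and restores the caller's RNG
state, so pipelines are reproducible end to end and the pipeline manifest
records md5 checksums to prove it. The shipped analysis drivers and the
test suite run at deliberately moderate sizes — 10–15 demes, 60×60 rasters,
hundreds of calibration replicates, 199-permutation Monte Carlo tests —
chosen so the whole suite completes on a laptop core in minutes while
keeping every binomial tolerance honest; the same functions scale to the
full field design (90 sites, 4,005 pairs, 9,999 permutations) by changing
arguments, not code.

## Known limitations

* Pairwise non-independence is unaddressed in the AICc models and the
  pair-level bootstrap, as discussed above.
* The exact null-allele estimator and exclusion threshold used for the
  published per-locus decisions are not documented at the source; both
  estimators are reported and the threshold is a config value
  (default 0.20).
* `optimize_feature_cost` optimizes features one at a time against the IBD
  baseline; interactions between features enter only at the additive model
  stage. Two features whose geometry separates the same demes are not
  identifiable there — the model table will split weight between them.
* The dbRDA embedding of raw (possibly negative) differentiation uses an
  offset plus Lingoes correction; both corrections are logged so either
  convention can be recovered.
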