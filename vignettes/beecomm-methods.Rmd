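---
title: "Methods: count-table statistics for honey bee gut communities"
author: "beecomm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: count-table statistics for honey bee gut communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beecomm)
```

## The problem

Honey bee foragers carry a small, conserved gut community - Orbaceae
(*Gilliamella*, *Frischella*), *Snodgrassella*, *Bifidobacterium*, the
*Lactobacillus* Firm-4 and Firm-5 clades, and a handful of
Acetobacteraceae-like alpha phylotypes. A natural field question is whether
this community differs between colonies that store a honey surplus
("productive") and colonies that do not. The design beecomm targets is 14
colony libraries - the most and least productive hive from each of seven
apiaries - with deep but very uneven 16S sequencing (25,000 to roughly
230,000 reads per colony) and extreme taxon dominance: a single
*Gilliamella* phylotype can account for half of a colony's reads.

Two statistical routes through such data exist, and they answer different
questions:

1. **Biological replicates.** Keep the 14 colonies as units, rarefy each
   library to a common depth, and test per-taxon differences
   (Kruskal-Wallis), multivariate separation (stepwise discriminant
   analysis on Wilks' lambda), and diversity/evenness. Noise between
   colonies is retained; n is small but honest.
2. **Pooled in-silico libraries.** Pool all reads within each productivity
   group, repeatedly draw fixed-size libraries from each pool, and compare
   per-taxon percentile intervals between groups. Between-colony
   variability is averaged away; the procedure is powerful but, as shown
   below, answers a question about the *pools*, not the *colonies*.

beecomm implements both routes, the co-occurrence network used to study
taxon masking, a co-culture interaction scorer for follow-up wet-lab
validation, and - because the underlying sequence libraries are not
available as a printed table - a synthetic community generator that
reproduces the design closely enough to exercise and calibrate every stage.

## The synthetic community generator

`sample_table()` draws colony `c` in group `g` as

$$p_c \sim \mathrm{Dirichlet}(\theta\, p_g), \qquad
  y_c \sim \mathrm{Multinomial}(L_c,\ p_c),$$

where `p_g` is the group's base composition, `L_c` the colony's library
size, and `theta` the concentration controlling between-colony dispersion.

* **Base composition** defaults to the per-colony average read counts of
  the thirteen core phylotypes (`core_microbiome_profile()`), normalised;
  both groups share it unless an `effect_spec()` enriches a taxon.
* **Library sizes** default to `round(runif(14, 25000, 230000))`: the floor
  is the smallest library in the surveyed design, the ceiling is of the
  order of the average sequencing yield per colony.
* **Concentration** defaults to `theta = 18.3`. The source data report only
  dispersion ranges, the clearest being a between-colony SD of roughly
  1,000 reads per 10,000 for the Orbaceae family (share `p = 0.739`).
  Matching the Dirichlet variance `p(1-p)/(theta+1)` to `sigma = 0.10`
  gives `theta = p(1-p)/sigma^2 - 1 = 18.3`. This is a calibration of
  scale, not a fitted parameter: one global `theta` cannot match every
  taxon's dispersion, and rare taxa (Dirichlet shape `theta * p` well below
  1) are more variable under this model than real biology may be.
  `concentration = Inf` switches inter-colony dispersion off entirely
  (colonies become i.i.d. multinomials), which is the correct null for
  calibrating the pooled-resampling procedure (below).
* **Effects** multiply the enriched group's base proportion and renormalise
  - compositional closure, since libraries have fixed size.
* **Reproducibility**: one root seed; every colony, stage, and scenario
  derives its own stream by name (`derive_seed()`), so results never depend
  on call order.

What the generator does *not* emulate: sequence-level error (chimeras,
misclassification), taxon-specific dispersion, phylogenetic correlation
between taxa, or apiary-level structure. Passing tests therefore show that
the *statistics* behave as intended under the stated sampling model, not
that real colonies obey that model.

## Rarefaction and pooled resampling

Rarefaction (`rarefy_counts()`, `rarefy_table()`) is an exact multivariate
hypergeometric draw, implemented as sequential conditional `rhyper()` draws
- taxon by taxon, conditioning on what remains of the pool and of the
library. This is exact and memory-light even for 10^5-read pools.

`group_resampling_ci()` implements the pooled route: pool counts within
each group, draw `N` libraries of `L` reads from each pool (default
`N = 100`, `L = 10000`, without replacement; the protocol text also
mentions 1,000 resamplings, so `N` is a plain override, and
`replacement = TRUE` is available), take per-taxon empirical percentile
intervals, and flag taxa whose intervals are disjoint. Numerical rules,
fixed for reproducibility:

* percentile rule: linear interpolation between order statistics
  (`quantile()` type 7);
* overlap rule: intervals sharing an endpoint count as *overlapping* - a
  conservative reading of "do not overlap".

**Calibration versus anticonservativeness.** When colonies are i.i.d.
draws from one shared composition (`concentration = Inf`), the two group
pools differ only by multinomial noise over ~10^6 reads, which is tiny
relative to the width of a 10,000-read library's percentile interval: the
procedure flags essentially nothing, and the acceptance suite verifies a
false-positive rate below 5% among taxa at or above 0.1% pool frequency.
But under realistic between-colony dispersion (`theta = 18.3`) the pooled
proportions of the two groups differ by inter-colony noise that the
in-silico intervals do not represent - so the procedure flags most common
taxa *even with no group effect*. The default pipeline run shows exactly
this. That is not a bug: it reproduces, and makes mechanical, the
discrepancy between in-silico and biological replicates that motivates
treating pooled-resampling significance with caution. Conclusions about
colonies should rest on the biological-replicate route; the pooled route
describes the aggregated pools only.

## Diversity

Shannon `H = -sum p_i ln p_i` (natural log throughout - the evenness
definition `E = H / ln S` fixes the base), richness `S` as the count of
nonzero taxa in the rarefied table, evenness undefined at `S = 1` and
returned as `NA` with a warning. Diversity is computed after rarefaction by
default, pairing it with the same input the discriminant analysis uses;
`diversity_table()` accepts any table if a different convention is wanted.
Group summaries are medians (midpoint rule for even groups).

## Kruskal-Wallis and stepwise discriminant analysis

`kruskal_wallis()` uses mid-ranks with the tie correction
`1 - sum(t^3 - t)/(n^3 - n)` and refers `H` to chi-squared with
`groups - 1` df (delegated to `stats::kruskal.test`; the tie factor is
reported alongside). At `n = 14` the chi-squared approximation is accurate
in the decision-relevant tail; exhaustive enumeration in the test suite
shows it undershoots the exact permutation p in the middle of the null
distribution, so mid-range p-values should be read qualitatively.
`kw_all_taxa()` applies no multiplicity correction by default, mirroring
the original single-subsampling analysis; `adjust = "BH"` adds
Benjamini-Hochberg adjusted p-values.

`stepwise_da()` is forward selection with backward removal on Wilks'
lambda, `Lambda = det(W)/det(T)`:

* entry: the candidate minimising `Lambda` enters if its Rao partial F,
  `((Lambda_p / Lambda_{p+1}) - 1)(n - g - p)/(g - 1)`, reaches `f_enter`;
* removal: any entered predictor whose partial F falls below `f_remove`
  leaves;
* defaults `f_enter = 3.84`, `f_remove = 2.71` - the classic stepwise
  thresholds, used because the source protocol reports SPSS-style stepwise
  output without naming its criteria (its printed first-step F is not
  reproducible from the printed lambda under any standard formula, so no
  attempt is made to match that configuration);
* ties in the entry criterion break by taxon label order - the trace is
  deterministic;
* the final model is summarised by Bartlett's chi-squared,
  `-(n - 1 - (p + g)/2) ln Lambda` on `p(g-1)` df, and by leave-one-out
  accuracy.

`loo_crossvalidate()` refits centroids and the pooled within-group
covariance without the held-out sample and classifies it by Mahalanobis
distance; distance ties go to the first group level, which keeps an
uninformative (constant) predictor at the balanced chance rate. The
predictor *set* is held fixed during leave-one-out; accuracy for a model
whose predictors were themselves selected on the same 14 samples is
therefore optimistic, and the permutation check in the acceptance suite
(fixed predictor set, permuted labels) is the calibrated reference point.
With 13 candidate predictors and 14 samples, the stepwise procedure will
occasionally assemble a nominally significant model from pure noise - a
caution the package deliberately leaves visible rather than papering over.

## Co-occurrence networks and compositional masking

`spearman_rho()` computes rho as the Pearson correlation of mid-ranks
(count data are tie-heavy; the `d^2` shortcut is valid only without ties
and agrees there). p-values: full permutation enumeration for `n < 10`
(exact, conditional on the tie pattern), t approximation
`t = rho sqrt((n-2)/(1-rho^2))` otherwise. `build_network()` keeps edges
with `p < 0.05` (unadjusted, mirroring the original analysis; a BH flag is
available), records `R^2 = rho^2` for edge sizing and the sign for
colouring, and `export_edges()` writes the tab-delimited table Cytoscape
loads directly. Correlations default to the family level in the pipeline
(`default_taxonomy()` folds the core genera into families, Orbaceae
containing *Gilliamella*, *Frischella* and gamma-2).

`masking_scenario()` demonstrates why dominance alone produces negative
edges. Each colony draws its dominant share from
`Beta(theta d, theta (1-d))` (`theta = 18.3`, the generator's dispersion
scale) while the *relative* composition of a fixed rare-taxon panel - 30
taxa with geometric weights `0.7^(i-1)` - is drawn with a larger
concentration (200): dominance fluctuates between colonies, the residual
community is comparatively stable. At fixed depth, every rare taxon's
counts then scale with `(1 - d)`, so the dominant taxon is negatively
rank-correlated with most of the panel, and the geometric tail sits near
the detection threshold so that mean detected richness falls as dominance
rises - both without any ecological interaction in the generator. The
panel's two concentrations are design choices of the demonstration, not
estimates; the geometric tail is what makes richness sensitive to
dominance at a 10,000-read depth.

The package deliberately stops at the same methods the original analysis
used: no partial correlations, no log-ratio (compositionality-aware)
association measures. Those are the principled alternative for real
inference; here the point is to show what the plain method does.

## Co-culture scoring

`coculture_analysis()` scores each strain pair at the day-3 endpoint:
expected OD from the two monoculture day-3 means, observed mean and SD from
the co-culture replicates, class `positive` / `negative` / `neutral` by
whether the deviation exceeds one replicate SD (strict inequalities; the
protocol's "outside the standard deviation"). Two choices the protocol
leaves open are surfaced as parameters rather than hidden:

* the combining rule for the expectation - `mean` (default; a 1:1 mixed
  inoculum approaching a shared carrying capacity), `sum`, or `max`;
* the SD used is the *co-culture* replicate SD (triplicates).

Classification is scale-equivariant (multiplying all ODs by a constant
preserves classes). Under pure Gaussian noise with *known* SD the neutral
class covers `2*pnorm(1) - 1 = 0.6827` of records, which the acceptance
suite verifies by simulation; with an SD *estimated* from triplicates the
corresponding probability is t-based and nearer 0.77 - worth remembering
when reading heat maps built from triplicate assays.

## Problem sizes and determinism

The test and acceptance suites run the full design at its native scale -
14 colonies, depths 25,000-230,000, 100 libraries of 10,000 reads - with
50 replicate pipelines for calibration and power properties, 1,000
Monte-Carlo colonies for richness curves, and 10,000 draws for
distributional checks; exact enumeration oracles (70 balanced
arrangements, 5! permutations) back the closed-form statistics. Everything
randomised flows from one root seed through named substreams, and a
pipeline run writes byte-identical outputs when repeated with the same
seed and configuration.

## Known limitations

* One global Dirichlet concentration; taxon-specific dispersion is not
  modelled.
* The pooled-resampling CI procedure is reported faithfully but is
  anticonservative across colonies under overdispersion (see above) - by
  design, as a demonstration.
* Discriminant analysis supports two groups in its classification methods;
  the lambda formulas are general but untested beyond two.
* No FDR control by default anywhere, mirroring the original analysis;
  BH flags exist for users who want them.
* Family assignment for the alpha-1 phylotype is left as its own bin; its
  placement varies in the literature.
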