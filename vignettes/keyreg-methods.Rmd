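---
title: "keyreg: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{keyreg: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keyreg)
```

## The problem

A *key regulator* of a transcriptional response is a transcription factor
or co-factor that (a) changes expression itself between conditions and
(b) drags a detectable set of target genes along with it. Neither signal
alone is sufficient: a differentially expressed TF with unresponsive
targets may be a passenger, and an enriched target set under a flat
regulator suggests the signal comes from elsewhere. keyreg scores both
channels and combines them.

The pipeline is four pluggable stages: differential expression, data-driven
regulator–target network inference, target-set enrichment, and a combined
score. Each stage is an exported function; `run_keyreg()` chains them and
`run_pipeline()` adds file I/O and a run manifest.

## Stage 1 — differential expression (the $P_D$ channel)

Counts (RNA-seq) are modelled per gene with a negative binomial GLM with
log link, a group covariate and log size-factor offsets
(`nb_wald_test()`). Size factors are median-of-ratios: the per-sample
median of counts over the gene's geometric mean, computed over genes
positive in every sample. Dispersions are method-of-moments estimates
from within-group variances, clamped to $[10^{-8}, 10]$ and shrunk
(geometrically, weight 0.5) toward a trend obtained by averaging
log-dispersion inside ten expression-level bins. The Wald statistic is
the group coefficient over its standard error with two-sided normal
p-values. This is a deliberately transparent re-implementation of the
standard count-DE recipe rather than a wrapper: the pipeline treats DE
as a pluggable stage, and the simplified model keeps the statistical
behaviour inspectable and fully testable (the suite checks its type-I
error on label-permuted null data).

Continuous data (microarray, proteomics; assumed log scale) use a
per-gene linear model with empirical-Bayes variance shrinkage
(`moderated_t_test()`): residual variances are shrunk toward a prior
fitted by matching moments of $\log s^2$ to a scaled inverse-chi-square
distribution (trigamma inversion), and the moderated t uses the augmented
degrees of freedom. With `prior_df = 0` it reduces exactly to the
ordinary equal-variance t-test; the test suite also verifies the shrunk
variances and p-values against the `limma` reference implementation.

Multi-group and time-series designs use nested-model likelihood-ratio
tests (`likelihood_ratio_test()`): Gaussian likelihood with profiled
variance for continuous data ($n\log(RSS_0/RSS_1)$ against
$\chi^2_{\Delta\mathrm{rank}}$), NB likelihood with fixed gene-wise
dispersion for counts.

All raw p-values are clamped to $\ge 10^{-300}$ so downstream $-\log$
transforms stay finite; adjustment is Benjamini–Hochberg throughout. The
differential gene set used by the enrichment stage defaults to
`p_adjusted < 0.05` (`de_fdr`), a conventional choice exposed as
configuration.

## Stage 2 — regulator–target network

Both backends produce a non-negative weight matrix with regulators as
rows and all genes as columns, from which `extract_topology()` keeps the
top-weighted fraction of candidate edges (default 5%) as a directed
regulator→target network.

**Co-expression (COEN).** Pearson correlation, unsigned adjacency
$a_{ij} = |r_{ij}|^\beta$, with $\beta$ chosen by the approximate
scale-free topology criterion: the smallest candidate power whose
connectivity distribution fits $\log_{10} p(k)$ vs $\log_{10} k$ with
$R^2 \ge 0.85$ over ten equal-width connectivity bins (plain $R^2$, no
slope-sign convention; if no power reaches the target the best-fitting
power is used with a warning). The adjacency is then converted to the
topological overlap measure
$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}},$$
which credits shared neighbourhoods as well as direct similarity.
TOM is symmetric; direction is imposed by restricting edge sources to
the declared regulator set. The regulator-row TOM is computed blockwise
(`block_size` columns at a time) so the full gene×gene matrix is never
materialised; integer powers use repeated squaring.

**Random forest (GRN).** Each gene is regressed in turn on the
regulators (excluding itself) with a random forest on per-gene
standardised expression (1000 trees, `mtry` $=\lfloor\sqrt{\#\mathrm{regulators}}\rfloor$,
minimum node size 1, via `ranger`). The weight of regulator $i$ for gene
$j$ is the impurity importance normalised so the column sums to the
model's out-of-bag $R^2$ (floored at 0), i.e. the fraction of variance
of gene $j$ the regulators explain. Models whose out-of-bag $R^2$ is
non-positive are removed entirely (`filter_poor_models()`): a gene the
regulators cannot predict contributes no edges. The threshold 0 is a
design choice — it is the natural "no better than the mean" boundary.
Per-target RNG seeds are drawn up front from the master seed, so results
are identical for any number of workers.

**Edge extraction.** Candidate edges are all unmasked regulator→gene
entries; exactly $\lceil f \cdot \#\mathrm{candidates}\rceil$ are kept,
with ties at the cutoff broken by weight descending, then regulator ID,
then target ID — reproducibility outweighs any claim that one tied edge
is better than another. Nodes left without edges are dropped.

**Hub metrics.** `hub_metrics()` reports out-degree and out-closeness.
For disconnected digraphs closeness is computed over the reachable set
with the Wasserman–Faust size correction
$(n_r/\sum d)(n_r/(n-1))$; nodes reaching nothing score 0. This is a
documented convention — closeness is undefined on disconnected graphs
and any finite choice is a convention.

## Stage 3 — enrichment (the $P_E$ channel)

**Over-representation (FET).** For a regulator with $s_i$ targets in the
network universe ($N$ nodes) and overlap $K$ with the $M$ differential
genes inside the universe, the p-value is the hypergeometric upper tail
$$P_i = \sum_{k=K}^{s_i} \binom{M}{k}\binom{N-M}{s_i-k}\Big/\binom{N}{s_i},$$
summed in log space. Differential genes outside the network are
excluded. The universe defaults to all network nodes and is overridable.

**Weighted GSEA.** The ranking metric is the z-scored $-\log p$ of all
network genes, sorted decreasingly (ties by gene ID; the log base is
irrelevant after standardisation, which the tests verify). Walking down
the list, hits accumulate $|r_j|$ normalised over the target set and
misses accumulate $1/(N-N_H)$; the enrichment score is the running
difference's maximum if that dominates the maximal deficit, otherwise
its minimum. The implementation evaluates the running sum only at hit
positions ($O(N_H)$ per set, since the sum decays linearly between
hits); the suite checks it against a full prefix recomputation oracle.

The null shuffles gene labels against metric positions — the paper-style
gene permutation rather than sample permutation — with one shared
permutation stream for all regulators (cross-regulator comparability and
speed). The empirical p is one-sided on the sign-matched side of the
null with a +1 pseudo-count in numerator and denominator, so p is never
0 and never exactly the naive rank. Regulators whose target set
intersects fewer than `min_set_size = 3` metric genes are reported NA: a
two-gene regulon cannot support a meaningful running-sum statistic.

## Stage 4 — the combined score

$$\mathrm{score} = f(-\log P_E) + f(-\log P_D), \qquad
f(x) = \frac{x - \min x}{\max x - \min x},$$
computed over the regulators present in the enrichment table. Min-max
normalisation makes the score invariant to the log base and to any
positive affine rescaling of either channel; a constant channel maps to
all zeros and contributes nothing. Regulators missing a DE p-value (not
expressed) or with NA enrichment get p = 1 in that channel. Ordering
ties break by smaller $P_E$, then smaller $P_D$, then ID, and ranks are
the resulting positions — every run yields one reproducible total order.

## The synthetic benchmark

`simulate_regulators()` emulates a two-state experiment with planted
ground truth: $m$ regulators with baseline means drawn once from
Gaussian(10, 2) (heterogeneous, positive, log-intensity-like scale;
per-regulator SD 1), of which the first $k$ have their group-B mean
shifted by `effect_size` (default two regulator SDs). Each regulator
drives $t \sim U\{3..50\}$ targets; a target is its regulator's
expression plus Gaussian noise (SD 1 by default), so the
regulator–target correlation is
$\sigma_x/\sqrt{\sigma_x^2+\sigma_\epsilon^2}$ by construction. At the
published scale ($m = 500$) the expected gene count is
$500 + 500 \times 26.5 = 13{,}750$ (SD $\approx 310$), matching the
reported single-draw realisation of 13,789.

`downsample_dataset()` draws balanced subsets without replacement
(50, 20, 10, 6 samples in the benchmark); `simulate_knockdown()`
multiplies one regulator by a knock fraction in the silenced group and
re-propagates its targets — an in-silico silencing experiment.

What the generator does *not* emulate: mutual-information-style
dependence, library-size and batch artifacts, overdispersion beyond the
optional Poisson counts mode, indirect cascades (targets depend on
exactly one regulator), and correlated regulators. Passing benchmarks
here therefore demonstrates internal correctness and sensible behaviour
under the stated generative model, not performance on real tissue data.

## Problem sizes used by the test suite

The acceptance-style tests run at desk scale, chosen so the whole suite
completes in minutes on one CPU while keeping each claim's structure
intact: the gene-count check runs at the published $m = 500$; the
down-sampling trend runs at $m = 150$, $k = 20$, $N = 100$ with effect
size 3 over 10 seeds and COEN+FET; the knockdown benchmark at $m = 200$
regulators (~5,500 genes), 20+20 samples, knock fraction 0.2, COEN+GSEA
with 1000 permutations over 20 seeds; null calibrations use 200 random
target sets (GSEA) and 40 simulations of 150 genes (NB Wald).

## Numerical conventions and degenerate inputs

* p-values clamped to $[10^{-300}, 1]$; BH within each result table.
* Constant genes are dropped with a warning before correlation;
  all-zero count genes report $p = 1$, fold change 0.
* Dispersion floor $10^{-8}$; fold changes use a 0.5 pseudo-count on
  normalised means.
* Tie-breaking is deterministic everywhere (documented per stage);
  all RNG flows through one seed per run; parallel workers never change
  results.
* `minmax` of a constant vector is all zeros; empty vectors error.

## Known limitations

* The NB Wald test is mildly anti-conservative at small sample sizes
  (measured type-I error ≈ 0.065 at $n = 10$ per group in the suite's
  null simulation) — inherent to plug-in dispersion Wald tests.
* COEN directionality is assumption, not inference: a symmetric
  similarity is oriented by declaring sources to be regulators.
* GSEA permutation p-values are bounded below by $1/(n_{perm}+1)$;
  ranking resolution among very strong regulators is limited by
  `n_perm`.
* The bundled regulator list is a synthetic stand-in of human TF
  symbols for out-of-the-box runs; real analyses should supply a
  curated list appropriate to the organism and platform.
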