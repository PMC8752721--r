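# keyreg

Key gene regulator ranking from expression data.

Transcriptional responses are driven by regulators — transcription
factors and co-factors — whose own expression change propagates to their
target genes. A regulator is worth calling *key* only when both signals
are present: it is differentially expressed between conditions **and**
its inferred target set is enriched in the differential signal. Hub
metrics alone (degree, closeness) do not capture this; keyreg scores the
two evidence channels explicitly and combines them.

The pipeline has four pluggable stages:

1. **Differential expression** — negative binomial Wald test for counts,
   moderated t with empirical-Bayes variance shrinkage for continuous
   (log-scale) data, likelihood-ratio tests for multi-group /
   time-series designs. Produces per-gene p-values `P_D`.
2. **Regulator–target network** — either COEN (Pearson correlation,
   soft-threshold power chosen by the approximate scale-free criterion,
   topological overlap measure) or GRN (per-gene random-forest
   regressions on the regulators; importance weights scaled to the
   fraction of variance explained, with poorly predicted genes
   removed). The top 5% of candidate edges (default) form a directed
   regulator→target network. User-supplied edge lists are accepted.
3. **Enrichment** — hypergeometric over-representation of the
   FDR-significant gene set in each regulon (FET), or a weighted GSEA
   enrichment score over the z-scaled −log p ranking metric with a
   1000-permutation gene-shuffling null. Produces per-regulator
   p-values `P_E`.
4. **Ranking** — the combined score

   ```
   score = f(−log P_E) + f(−log P_D),   f(x) = (x − min x) / (max x − min x)
   ```

   over the regulator set, sorted with deterministic tie-breaking.

A synthetic benchmark generator with planted key regulators, balanced
down-sampling and in-silico knockdowns makes every stage testable
without any external data.

## Worked example

Simulate a two-group experiment with 50 regulators (5 of them true key
regulators, group shift of 3 SDs), then run COEN + GSEA:

```r
library(keyreg)

spec <- simulation_spec(n_samples = 40, n_regulators = 50, n_bona_fide = 5,
                        effect_size = 3, seed = 7)
ds <- simulate_regulators(spec)
ds
#> simulated_dataset: 1382 genes (50 regulators, 5 bona fide) x 40 samples

res <- run_keyreg(ds$expression, ds$regulators,
                  network_method = "coen", enrich_method = "gsea",
                  n_perm = 1000, seed = 7)
head(res$ranking, 6)
#>   rank regulator      p_d log_fc      p_e    es n_targets overlap score
#> 1    1       R02 1.72e-13  3.262 0.000999 0.977       248     248  2.00
#> 2    2       R04 5.23e-12  3.081 0.000999 0.980       229     229  1.88
#> 3    3       R05 1.81e-11  2.991 0.000999 0.966       255     255  1.84
#> 4    4       R03 2.73e-11  2.943 0.000999 0.980       234     234  1.83
#> 5    5       R01 2.33e-08  2.477 0.000999 0.975       225     225  1.60
#> 6    6       R36 3.15e-01  0.426 0.001036 0.726        44      44  1.03

ds$truth
#> [1] "R01" "R02" "R03" "R04" "R05"
```

All five planted regulators are recovered at ranks 1–5. Reading the
columns: `p_d` is the regulator's own differential p-value (`log_fc` its
log2 fold change), `p_e` the permutation p-value of its target-set
enrichment (`es` the enrichment score, here at the 1/1001 permutation
floor for the planted regulators), `n_targets` the regulon size in the
network, and `score` the combined min-max score in [0, 2] — the planted
regulators separate cleanly from the best null regulator (score 1.03,
driven by its enrichment channel alone while `p_d = 0.32`).

Directed hub metrics for comparison:

```r
hm <- hub_metrics(res$network)
head(hm[order(-hm$out_degree), ], 3)
#>   node out_degree out_closeness
#> 2  R05        255         0.226
#> 6  R02        248         0.184
#> 1  R03        234         0.183
```

`run_pipeline(config)` performs the same run from TSV files (expression
matrix, sample metadata, regulator list, optional user network) driven
by a YAML config, writing every stage's table plus a
`run_manifest.json`, and `exec/keyreg` exposes the stages as shell
subcommands (`simulate`, `de`, `network`, `enrich`, `rank`, `hubs`,
`run`).

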