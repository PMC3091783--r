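# dister

Operon map inference for reduced bacterial genomes.

Bacterial genes are transcribed in transcription units (TUs): one gene
(monocistronic) or several adjacent same-strand genes (polycistronic,
operons) read into a single mRNA. Reduced endosymbiont genomes — the kind
that have lost most transcription-factor repertoires — are poorly served by
operon predictors that lean on functional similarity or cross-genome
conservation, because genome erosion and rearrangement have assembled
operons out of functionally unrelated genes. `dister` predicts operon maps
from **structural evidence alone**: the intergenic distance between
adjacent genes and predicted Rho-independent terminators. It is aimed at
microbial genomicists who have a gene annotation, a TransTermHP terminator
scan, and (for training) a curated TU collection from a well-studied
relative.

## The model

For each adjacent same-strand gene pair the classifier computes the
posterior probability that the pair is co-transcribed ("same TU", STU)
rather than split across TUs (DTU):

```
P(STU | x) = p · P(x | STU) / [ p · P(x | STU) + (1 − p) · P(x | DTU) ]
```

where `x` is the pair's feature cell — the intergenic distance binned in
10-bp intervals (`floor(d/10)`, negative for overlapping genes), joined
with terminator evidence — and the class-conditional tables `P(x | c)` are
add-α-smoothed relative frequencies estimated from labeled training pairs.
Three configurations are supported: (1) distance and terminator presence as
independent marginals; (2) their joint distribution (the default); (3) the
joint distribution of distance and a four-level terminator score class.

The prior `p` comes from a geometric model of TU length: if
`P(L_TU = n) = p^(n−1)(1 − p)` then the mean TU length is `1/(1 − p)`, so
`p = (mean − 1)/mean`. A pair is called STU when its posterior strictly
exceeds the decision threshold (default 0.5); calls are chained into
maximal co-transcribed runs, which partition the genome into an operon map.

Around the classifier the package provides the full study workflow:
threshold scans under resubstitution, stratified 80/20 holdout and
leave-one-out schemes with nearest-corner threshold selection; map-level
statistics and geometric fits; expression-based validation (one-way ANOVA
of per-gene log-expression on TU membership, with a length-preserving
TU-label permutation null); comparative analyses against a reference
genome (five-class TU typing, ancestral pairs and fragments, six-class
coding-length evolution, BBH orthology); and a seeded synthetic-data
generator with an analytic Bayes-optimal oracle.

## Worked example

Simulate a 1,000-gene circular genome with known operon structure, train
configuration 2 on its labeled pairs, predict, and assemble the map:

```r
library(dister)
library(dplyr)

cfg <- simulation_config(n_genes = 1000)
sim <- simulate_genome(cfg, seed = 42)

train <- filter(sim$pairs, orientation == "same_strand")
model <- dister_fit(train, config = 2, alpha = 1, prior = "empirical")
model
#> <dister_model> config 2 | prior P(STU) = 0.6823 (empirical) | alpha = 1
#>   trained on 524 STU + 244 DTU pairs, bins -2..30, threshold 0.50

calls <- bind_rows(
  dister_classify(model, train, threshold = 0.5),
  mutate(filter(sim$pairs, orientation != "same_strand"), call = "DTU"))
map <- assemble_map(sim$annotation, calls)
map_stats(map)
#> # A tibble: 1 × 6
#>   n_genes n_tus n_mono n_poly mean_len mean_poly_len
#> 1    1000   454    209    245     2.20          3.23
```

454 TUs from 1,000 genes means 546 pairs were called co-transcribed
(`n_tus = n_genes − #STU calls` on a circular map); the mean TU carries
2.20 genes, the mean operon 3.23. Against the simulator's ground truth
these calls are 91.9% accurate — compare the analytic optimum of the
generating law, `bayes_optimal_rates(cfg)`: Se 0.96, Sp 0.83.

Validate the map against (simulated, within-TU-correlated) expression:

```r
expr <- simulate_expression(sim$truth_map,
                            simulation_config(n_genes = 1000, rho = 0.6),
                            seed = 43)
permutation_pvalue(expr, map, n_perm = 1000, seed = 44)
#> <tu_permutation> F = 5.398, adj. R2 = 0.576, p = < 0.001
#>   (0 of 1000 simulated maps exceed; mode blocks_in_order, seed 44)
```

TU membership explains 58% of expression variance (adjusted R²), and no
map with the same TU lengths laid elsewhere on the chromosome matches the
observed coherence. Evaluation-scheme scans work the same way:

```r
glance(threshold_scan(train, config = 2, scheme = "holdout", seed = 45))
#> # A tibble: 1 × 7
#>   scheme  n_thresholds n_fits chosen_threshold    se    sp   cost
#> 1 holdout           20      1             0.55 0.933 0.878 0.0194
```

`autoplot()` methods draw the ROC-style scan, the TU-length histogram with
its geometric fit, and the permutation null. A thin command-line wrapper
(`exec/dister`) chains the same steps as subcommands (`simulate`, `pairs`,
`train`, `predict`, `assemble`, `evaluate`, `map-diff`, `compare`,
`validate-expression`) for shell pipelines; every output gets a
`.meta.json` sidecar recording version, parameters and seed.

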