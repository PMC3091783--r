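---
title: "Inferring operon maps from intergenic distance and terminator evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring operon maps from intergenic distance and terminator evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dister)
library(dplyr)
```

## The inference problem

An operon map assigns every gene of a bacterial replicon to exactly one
transcription unit (TU). Deciding the map reduces to a binary call on each
adjacent same-strand gene pair: co-transcribed (STU) or not (DTU). Pairs on
opposite strands are DTU by definition. Chaining the calls gives the map:
TUs are maximal runs of consecutive same-strand genes whose internal pairs
are all STU, so on a circular replicon with at least one DTU call,
`#TUs = #genes − #STU calls`.

`dister` makes the pair call from two structural features only:

* **intergenic distance** — base pairs strictly between the two coding
  sequences, negative when they overlap; co-transcribed genes sit close
  (the distance distribution of known operon pairs peaks between −20 and
  +30 bp), while TU borders carry promoters and terminators and tend to be
  wider. Distances enter the model in 10-bp bins, `floor(d/10)`, which
  keeps the class-conditional tables estimable from a few hundred curated
  pairs;
* **Rho-independent terminator evidence** — predicted terminator hairpins
  (e.g. TransTermHP calls with a 0–100 confidence). A terminator between
  two genes marks a TU 3' end, evidence *against* co-transcription.

The deliberate restriction to structural features makes the predictor
portable to genomes whose operons were assembled by rearrangement out of
functionally unrelated genes — exactly the situation in eroded
endosymbiont genomes, where functional-similarity and conservation
features mislead.

## The classifier

For a pair with feature cell `x`, Bayes' rule over the two classes gives

$$P(\mathrm{STU}\mid x) \;=\;
\frac{p\,P(x\mid \mathrm{STU})}
     {p\,P(x\mid \mathrm{STU}) + (1-p)\,P(x\mid \mathrm{DTU})}.$$

Three configurations define `P(x | c)`:

1. independent marginals of distance bin and terminator presence;
2. the joint distribution of (bin, presence) — the default, and the
   configuration whose resubstitution and generalization optima coincide;
3. the joint distribution of (bin, score class), with the confidence
   discretized as absent / low (< 76) / mid (76–90) / high (> 90). The
   cut points follow TransTermHP practice, where ≥ 90 is treated as
   high-confidence; the source collections give no explicit cuts.

**Smoothing.** Class-conditional tables are add-α relative frequencies
(default α = 1) over the grid spanned by the training bins × all
terminator states. Training collections never populate every cell that a
new genome will query; unsmoothed zero likelihoods would produce 0/0
posteriors. Bins outside the trained range are clamped to the nearest
trained edge bin, so an extreme spacer is treated as "at least as extreme
as anything seen in training" rather than falling off the table.

**Prior.** The default prior is geometric: assuming the number of genes
per TU follows `P(L = n) = p^(n−1)(1−p)`, the mean TU length is
`1/(1−p)`, hence `p = (mean − 1)/mean`; the mean is taken over the
experimentally-evidenced training TUs after leader-peptide exclusion
(`mean_tu_length()`), since those are the units the labels come from. An
empirical mode (STU fraction of the training pairs) is provided for
sensitivity analysis, and is what the synthetic-recovery workflows use
(see below).

**Decision rule.** STU iff the posterior strictly exceeds the threshold;
a posterior exactly at the threshold is DTU. The default threshold is 0.5;
`threshold_scan()` + `best_threshold()` implement the alternative of
scanning thresholds in [0.05, 1] (step 0.05, the resolution at which such
scans are usually reported; finer grids are accepted) and picking the
point minimizing `(1−Se)² + (1−Sp)²`, the squared distance to the perfect
corner of the ROC plane. Ties break toward 0.5, then toward the smaller
threshold, so the choice is deterministic.

## Training labels

From a curated TU table (`read_known_tus()`), `label_pairs()` derives:
STU if both genes are adjacent within at least one experimentally-evidenced
TU — where alternative overlapping TUs exist, one containing TU suffices;
DTU for opposite-strand pairs, and for pairs where exactly one gene belongs
to an experimental TU that excludes its partner; NK ("not known") when the
only TU containing both is a computational prediction. `training_pairs()`
keeps same-strand STU/DTU pairs and drops NK pairs and anything touching a
leader-peptide operon: attenuation operons are structurally atypical for
target genomes that lack attenuation altogether.

One rule is genuinely ambiguous in the sources: "only one gene belongs to
an experimentally determined TU" does not say what to do when the other
gene belongs to *no* TU at all. We label such pairs DTU only when the
covered gene's TU excludes the partner (membership elsewhere is positive
evidence of a border between them) and leave the pair `unlabeled` when
neither gene has experimental coverage — unlabeled pairs never enter
training.

## Terminator-to-pair assignment

The sources do not specify how a terminator call attaches to a pair. We
use the simplest rule consistent with terminators acting at a TU's 3' end:
a call counts for a pair iff its interval intersects the open intergenic
interval `[end_up + 1, start_dn − 1]` *and* its strand equals the upstream
gene's strand; among several, the highest-confidence call wins. Two
consequences worth noting: overlapping or abutting pairs (distance ≤ 0)
can never host a terminator, and divergent regions never receive one
(the upstream gene of a divergent pair points away from the region), so
per-orientation terminator tables report 0 for divergent regions by
construction.

## Evaluation schemes

`threshold_scan()` evaluates Se (true STU called STU) and Sp (true DTU
called DTU) under resubstitution (fit and score on all pairs — an
optimistic bound), a seeded label-stratified 80/20 holdout (stratification
protects the rarer class in small collections), and leave-one-out (N
refits, each classifying its held-out pair once; the N single-pair
outcomes pool into one confusion table per threshold). The geometric
prior, when used, is supplied per fold, and the empirical prior is
recomputed inside each training fold, so nothing leaks from held-out
pairs. Published holdout curves of this kind do not state whether they
average several splits; we implement a single seeded split and expose the
seed.

## Expression validation

`anova_tu()` regresses per-gene log-expression on TU membership over the
polycistronic TUs only (monocistronic TUs are excluded first — they
contribute no within-TU information and would inflate the group count):
`F = (SSB/(g−1))/(SSW/(n−g))`, `R²adj = 1 − (1−R²)(n−1)/(n−g)`. The input
granularity is one scalar per gene (replicates pre-averaged); stacking
conditions as replicates is possible by repeating gene rows. `SSW = 0` is
reported as `F = Inf`, a perfect-separation sentinel; a table with no
variance at all reports `F = 0`.

`permutation_pvalue()` builds the null by shuffling TU labels while
conserving the multiset of TU lengths. The default mode
(`blocks_in_order`) permutes the polycistronic TU lengths and re-lays them
as contiguous blocks over the chromosome-ordered polycistronic genes, so
simulated co-members remain neighbours — the null keeps gene proximity and
destroys only the placement of TU borders, which is precisely the
hypothesis under test (do borders, i.e. promoters and terminators,
partition expression beyond mere proximity?). `free_relabel` destroys
proximity too. The p-value is the proportion of simulated F values
*strictly* above the observed F; zero exceedances print as `< 1/n_perm`
while the raw 0 is kept in the JSON. With all TU lengths equal, every
block permutation reproduces the observed grouping and the strict rule
gives p = 0 — a documented tie artefact, not significance; maps that
degenerate this way need `free_relabel`. Whether label shuffling should
extend over monocistronic genes as well is ambiguous in the sources; the
default operates on the polycistronic subset (matching the ANOVA's
universe), and both modes are exposed.

## Comparative analyses

Against a reference genome's TU collection (nested alternative TUs reduced
to maximal ones, since one class must be assigned per TU), each TU is
typed by where its genes' orthologs live: `identical` (one reference TU,
exact correspondence), `similar` (one longer reference TU whose extra
genes have no ortholog anywhere — pure loss/acquisition), `split` (an
extra gene's ortholog lives in another TU), `merged` (several reference
TUs, no leftover ortholog elsewhere), `reorganized` (several, with a
leftover ortholog elsewhere). Mixed leftovers — some absent, some
relocated — count as reorganized; the evidence column records the
relocated genes. Orthology is bidirectional best hit (`bbh_orthologs()`),
appropriate for lineages without post-divergence duplication; score ties
break lexicographically and are flagged.

Ancestral pairs (`ancestral_pairs()`) are adjacent pairs whose orthologs
are also adjacent in the reference, in any relative orientation, or
failing that in a supplied outgroup; a `strict` flag demands
order-preserving (syntenic) adjacency instead. Maximal runs of ancestral
pairs form fragments (`k` pairs span `k + 1` genes). Coding-length
evolution is classified by the printed six-class scheme comparing each
gene's length in the focal genome, the reference and an outgroup; the
classes partition all complete triples and a missing outgroup length
yields `NA`, never a silent class. `loss_attribution()` scores a
reference gene absent from the focal genome as ancestrally present (and
lost) if any ancestor/outgroup source shows it, acquired in the reference
lineage if all sources are negative, and ambiguous with no usable
evidence — structural RNAs with unresolvable orthology end up here.

## The synthetic-data generator

`simulate_genome()` draws TU lengths from the geometric law until the gene
budget is spent (the final TU is truncated at the chromosome end — the
unbounded geometric model must be cut somewhere and truncation preserves
the partition), assigns each TU an independent random strand, draws every
within-TU pair's distance bin from the STU model and every between-TU
pair's from the DTU model, and lays gene coordinates accordingly; the
wrap-around pair draws from the non-negative part of its model so the
circle closes. Terminators are placed per class: 0.05 within TUs, 0.6 in
same-strand borders, 0.86 in convergent regions, never in divergent ones,
and — matching the assignment rule — only where the intergenic interval
has room (`P(term | bin < 0) = 0`). Because of that constraint the
features recomputed from coordinates and terminator calls equal the drawn
features exactly, and the analytic oracle `bayes_optimal_rates()` can
enumerate the law cell by cell with no sampling.

Default distance models: within-TU bins −2..3 peaking just above zero
(probabilities 0.08/0.12/0.30/0.25/0.15/0.10), the canonical compact-operon
shape including overlaps; between-TU bins 0..30 with geometrically
decaying mass (`∝ 0.87^bin`), the right-skewed, mode-at-zero shape typical
of intergenic spacing. Both are config data, not code constants, so tests
can probe edge regimes (disjoint supports, identical distributions).

Expression: gene value `√ρ·σ_b·b_TU + √(1−ρ)·σ_w·e`, with standard-normal
TU effects and gene noise. With the default σ_b = σ_w = 1 the within-TU
correlation equals ρ exactly, and ρ = 0 reduces to i.i.d. noise — the
regime used for permutation-calibration checks.

One statistical subtlety the generator makes visible: the geometric
parameter `p` is the co-transcription rate among *all* adjacent pairs, but
the classifier's universe is *same-strand* pairs, and with random TU
strands only half the between-TU pairs are same-strand, so the base rate
there is `p / (p + (1−p)/2)` (≈ 0.69 at p = 0.53). `bayes_optimal_rates()`
defaults to this same-strand prior, and the synthetic recovery workflows
fit with the empirical prior for consistency with the generative law. On
real genomes, where strand runs are longer than independence predicts, the
geometric prior remains the default operating point.

What the generator does **not** emulate: nucleotide sequence and AT
composition, gene-length/function correlations, transcription-factor
structure in expression, condition-dependent expression, overlapping
alternative TUs, and real terminator-prediction noise (false TransTermHP
calls inside operons). Green tests on synthetic data therefore certify the
statistical machinery — estimation, calibration, assembly, bookkeeping —
not transferability of a trained model across genomes, which depends on
how well the training genome's distance/terminator distributions match the
target's.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout (GenBank convention); GFF3
  I/O converts at the boundary. Circularity defaults to `TRUE` when file
  metadata is silent, matching bacterial chromosomes.
* The wrap-around pair participates in features, classification and
  assembly exactly like interior pairs; a whole-circle single TU is
  permitted but flagged degenerate.
* TU ids are deterministic (`TU_` + first gene in transcription order),
  so identical inputs give byte-identical outputs.
* Model JSON round-trips numerically exactly (no digit truncation);
  posterior equality after reload is tested to 1e-12.
* Conditional tables sum to 1 within 1e-12 by construction; the posterior
  of a pair with identical class tables equals the prior, a property used
  as a degenerate-case test.
* TU-length distributions are compared with a two-sided
  Wilcoxon–Mann–Whitney rank-sum test (independent samples, normal
  approximation), the standard choice for shifted discrete length
  distributions.
* Sums of squares for the permutation ANOVA are computed from cumulative
  sums over contiguous blocks, making the 10,000-replicate default (and
  the 400-run calibration sweep) cheap.

## Problem sizes

The test suite runs classifier recovery at 5,000 genes, simulator
calibration at 20,000 genes, parameter-recovery curves at 200/2,000/20,000
pairs, permutation calibration as 400 runs of 1,000 permutations, and
leave-one-out on collections of tens of pairs; `scripts/acceptance.R`
uses the same sizes. These sizes put standard errors well below the
tolerances being asserted while keeping a full run in the minutes range.

## Known limitations

* The classifier sees two features only; where functional or conservation
  signal is reliable, richer predictors can outperform it — the design
  trades peak accuracy for robustness to rearranged, eroded genomes.
* Add-α smoothing with α = 1 is mildly informative in sparsely populated
  score-class grids (configuration 3 divides the data eight ways); α is
  exposed and the α → 0 behaviour is property-tested.
* The holdout scheme evaluates one seeded split, not an average over
  splits; leave-one-out is the low-variance alternative provided.
* `assemble_map()` requires a call for every adjacent pair and treats the
  calls as hard; propagating posterior uncertainty into map-level
  statistics is out of scope.
* Known-TU tables are trusted as curated: gene ids must resolve against
  the annotation (checked), but coordinates are not cross-validated
  against TU extents.
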