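---
title: "Methods: cross-study host classification of gut microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-study host classification of gut microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hostclass)
```

`hostclass` builds pet/human host classifiers from genus-level 16S count
tables pooled across independent studies, and quantifies how much such
models overfit to the studies they were trained on. This vignette explains
the statistical choices behind each stage, the tunable parameters and their
defaults, what the synthetic generator does and does not emulate, and the
design decisions taken where more than one reasonable construction exists.

## Data model

A feature table is a samples × taxa matrix of non-negative integer read
counts. Taxa are identified by six-rank semicolon-delimited lineages
(kingdom;phylum;class;order;family;genus); a table "at level k" carries
lineages truncated to k ranks, and aggregation to a higher rank sums
counts over lineage prefixes, so per-sample read totals are conserved at
every rank. Taxa unassigned at a rank are labelled
`unclassified <parent>` so they group deterministically under their
deepest named ancestor. Counts stay integers; relative abundances are
closed on demand and never stored, which rules out accidental double
normalization.

Rare-feature filtering removes a taxon only when the fraction of
zero-count samples is *strictly greater* than the threshold (default 0.9)
in the pet class **and** in the human class. "Over 90%" is read literally:
a taxon at exactly 90% zeros in either class is kept. Retaining taxa that
are common in only one host is deliberate — host-exclusive taxa are among
the strongest classification signals.

## Chao1 under repeated subsampling

Richness uses the bias-corrected Chao1,

S_chao1 = S_obs + F1 (F1 − 1) / (2 (F2 + 1)),

with S_obs the observed taxa, F1 the singletons, F2 the doubletons. The
bias-corrected variant is chosen because it is defined when no doubletons
are observed. To damp the influence of low-abundance taxa at uneven
sequencing depth, the reported value is the mean of Chao1 over five
subsamples of exactly 5000 reads, each drawn without replacement at the
read level (multivariate hypergeometric, via `vegan::rrarefy`). Samples
shallower than the depth are dropped with a warning rather than
up-sampled: inventing reads would fabricate singletons, which is exactly
what Chao1 is sensitive to. When a sample totals exactly the depth, every
subsample is the full sample and the replicate variance is zero.

## Project-median differential abundance

Pooling samples across studies and testing them as independent
observations would let a single large study dominate and would conflate
batch effects with host effects. Instead each project is reduced to its
median relative abundance per taxon, and a two-sided Mann–Whitney test
compares the pet projects' medians against the human projects' (12 versus
10 in the reference design). The exact null distribution of the rank-sum
statistic is used when both groups have at most 12 values and the pooled
data are tie-free — which covers the reference design — otherwise the
tie-corrected normal approximation with continuity correction. Two
identical constant groups return p = 1. Because the test is rank-based it
is invariant to monotone transforms of the abundances.

Multiplicity is controlled both ways at alpha = 0.05 (the conventional
default; configurable): Holm–Bonferroni (step-down FWER) and
Benjamini–Hochberg (step-up FDR). The Holm-rejected set is always a
subset of the BH set at equal alpha; the two selections define the
restricted "MW-Holm" and "MW-FDR" model variants. The rarefied Chao1
value is tested with the same project-median procedure but reported
separately; it never enters the feature sets.

A consequence of exactness worth knowing: at 12-vs-10 the attainable
significance level at alpha = 0.05 is P(p ≤ 0.05) = 0.0426, not 0.05 —
discrete tests reject slightly less often than nominal. The calibration
tests account for this.

## Compositional transforms

The centred log-ratio transform maps a composition to unconstrained real
space: per sample, add a pseudocount (default 1 read) to every count,
close to proportions, and subtract the log geometric mean from each log
proportion. Rows of a CLR matrix sum to zero and the transform is
invariant to positive scaling of a row. The integer pseudocount is the
simplest defensible zero policy; multiplicative replacement strategies
exist but are not the default because the classifier results are
insensitive to the choice. When a restricted feature set is used, CLR is
computed on the full filtered table first and columns are selected
afterwards (transform-then-subset), matching how a practitioner would
apply it. Bray–Curtis dissimilarity, 1 − 2 Σ min(u, v) / (Σu + Σv), is
provided for ordination and for the generator's batch-effect diagnostics;
embedding methods themselves (t-SNE and friends) are left to external
tools via the distance-matrix writer.

## Balanced dataset construction

Training sets are balanced by host; the per-class target defaults to the
minority class total, so the minority class (pets, 321 samples in the
reference design) is taken in full. The majority class is down-sampled
with per-project quotas computed by water-filling: all projects share an
equal quota, projects smaller than the share contribute everything, the
shortfall is re-spread over the rest, and the final integer remainder
goes one sample at a time to the projects with the most remaining
samples (ties by project id). On the reference human pools
(681, 200, 115, 102, 49, 31, 22, 21, 12, 9) with target 321 this yields
quotas 46, 45, 45, 45, 45, 31, 22, 21, 12, 9. The exact algorithm behind
those published per-project counts is not documented anywhere we know of;
water-filling is a reconstruction that reproduces them and is stated here
as such. With `replacement = TRUE` quotas ignore pool sizes — the mode
the learning curve uses when a few projects must supply a whole class.

Mixed-species evaluation sets (default 100 sets of 50 cats + 50 dogs +
100 humans, each drawn without replacement) support averaging performance
metrics over resampled test compositions.

## The random-forest protocol

The design matrix is the selected taxa's relative abundances (or CLR
values) plus one column of mean Chao1 richness; "human" is class 1.
Hyperparameters follow the forest's standard knobs: candidate features
per split (2..p), maximum tree depth (2..52), minimum node size to split
(2..52), and tree count {1, 5, 10, 50, 100, 500, 1000}. Searching that
product space exhaustively is wasteful, so selection is two-step under
stratified 5-fold CV mean accuracy: step 1 evaluates a coarse Cartesian
grid — features per split {2, √p, p}, depth and min-split {2, 12, 32,
52}, trees {10, 100, 500}, spanning each range at low cost — and step 2
refines one parameter at a time over its fine range (every integer for
depth and min-split, a 25-point geometric ladder for features per split,
the full tree-count set), updating each before moving to the next. Ties
always resolve toward the simpler model: fewer trees, then shallower,
then larger min-split, then fewer candidate features.

The final model is refit on the whole balanced dataset 10 times,
differing only by seed, and out-of-bag accuracy, precision, recall and F1
(positive class "human", threshold 0.5) are reported as mean ± SD across
refits. The SD's replicate unit is a design decision: refit variation
isolates the forest's own sampling noise at fixed data. A fit errors if
any sample is in-bag for every tree, since its OOB vote would be
undefined — use more trees. Feature importances are impurity-based,
normalized to sum to 1 and averaged over refits; the overlap statistic
reports the fraction of the top-k importance-ranked taxa (Chao1 column
excluded) that lie in the k-taxon Mann–Whitney set. Prediction refuses a
design whose columns are not identical, in order, to the training design:
a permuted matrix is an error, never a silent misprediction. One
implementation subtlety: `ranger` draws a vote tie-break seed from the
global RNG unless given one, so every internal predict call passes an
explicit derived seed.

## The project learning curve

With N human projects, training sets are built for each n in 1..N−1 from
combinations of n projects drawn from the first N−1 (one project is
always reserved for testing, so the held-out set is never empty), capped
at min(200, C(N−1, n)) distinct combinations. The pet side is always the
full pet pool; the human side is sampled with replacement,
project-balanced, up to the per-class size (the pet total by default) —
with one project and 321 slots, replacement is unavoidable. Each
combination is resampled 5 times; plain accuracy is measured on every
human project absent from training, and the curve reports the mean per n
over combinations, resamples and test projects. Hyperparameters are
frozen (from a prior two-step search or supplied directly) rather than
re-searched per resample: the procedure evaluates how a *given* model
family transfers, and re-searching hundreds of times would be
disproportionate. Desk-scale defaults used by the tests are cap 20 and 2
resamples with a 64-tree forest; the full protocol (200/5) is a
configuration flag.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
with full ground truth. Per sample, each taxon's log-intensity is

baseline + δ·[host = human] + project shift + sample noise,

host-exclusive taxa are zeroed in the wrong host, intensities are
exponentiated and closed, and counts are drawn multinomially at fixed
depth (5000 reads). Defaults: 60 genera in 25 families across 8 phyla;
baselines N(0, 1) in log space; per-(project, taxon) batch shifts
N(0, 0.8²); per-sample noise N(0, 0.6²); 12 pet projects of sizes
65, 44, 30, 19, 6, 34, 32, 30, 23, 19, 13, 6 and 10 human projects of
sizes 46, 45, 45, 45, 45, 31, 22, 21, 12, 9 (the reference design's
training layout; a 4+4 × 10 "tiny" preset serves fast tests).

Two design points deserve emphasis:

* **Paired planted effects.** Eight genera carry a host effect of
  magnitude δ = 2 (≈7.4-fold), planted in balanced pairs: a
  human-elevated taxon and a pet-elevated mirror share a base intensity,
  so the expected total microbial load is identical in both hosts. Hosts
  "swap usage" of taxa — as real carnivore/herbivore guts swap Clostridia
  families — rather than one host carrying uniformly more of everything.
  Without the pairing, closure makes every null taxon's *proportion*
  genuinely host-differential (if some taxa rise, all others' fractions
  must fall), which both inflates apparent false positives and
  misrepresents the biology being emulated.
* **Sparse exclusive markers.** One human-only genus (its own
  Verrucomicrobia-like phylum, an Akkermansia-style marker) and one
  pet-only genus (Fusobacteria-like) are hard zeros in the excluded host
  but get a low baseline (−4, about one read per sample at depth 5000),
  so they behave like sparsely detected markers whose detection rate
  varies across projects, not like a perfect presence/absence label that
  would make classification trivial.

Batch strength deserves a note. At the default σ_batch = 0.8 the
generator already reproduces severe study-level overfitting: a forest
trained on one human project scores below 0.2 on held-out human projects
while plateauing above 0.95 once five or more projects contribute — the
learning-curve acceptance test asserts exactly this shape (n = 1 at
least 0.05 below the plateau; at least 80% of the rise attained by
n = 5), averaged over three generator replicates. Pushing σ_batch to 1.2
and beyond degrades the plateau itself: batch variation then swamps the
host effect and no cross-study classifier exists, which is a different
pathology than overfitting and is left out of the acceptance conditions.

What the generator does **not** emulate: sequencing error, chimeras and
primer-bias mechanisms; correlated abundance structure within taxonomic
families; realistic taxon name composition; overdispersion beyond the
log-normal sample noise; uneven read depths. Tests passing on this
generator therefore demonstrate that the *pipeline machinery* is correct
and calibrated under its stated model — not that any particular accuracy
carries over to real sequencing data.

## Numerical and reproducibility choices

* Every stochastic stage derives its own 32-bit seed from a global run
  seed plus a stage label, so stages are reproducible in isolation and
  manifest-driven reruns are byte-identical.
* Mann–Whitney exactness cutoff: both groups ≤ 12 and no ties (covers
  the 12-vs-10 design); otherwise tie-corrected normal approximation
  with continuity correction; all-tied input returns p = 1.
* Degenerate inputs error early with typed conditions: all-zero samples
  for Chao1, empty feature sets, single-class labels, samples missing
  from metadata (named in the message), thresholds outside [0, 1].
* Problem sizes in the tests are the desk-scale ones stated above
  (tiny layouts for unit tests; the study-scale 642 × 60 layout for
  recovery and the learning curve with cap 20, 2 resamples, 64 trees,
  3 replicates) — chosen as the smallest sizes at which the assertions
  are statistically meaningful.

## Known limitations

Accuracy, not AUC, is the headline metric (the decision threshold is
fixed at 0.5); probability calibration is out of scope. The quota
algorithm is a reconstruction (see above). The learning curve evaluates
held-out *human* projects only — the pet pool is always fully in
training, so pet-side study overfitting is not measured. The generator's
independence assumptions make multiplicity control slightly conservative
relative to data with strong taxon-taxon correlation.
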