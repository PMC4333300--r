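---
title: "Ranking compounds against protein targets: methods and design"
author: "RankVS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking compounds against protein targets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Ligand-based virtual screening asks, for a protein target, which of many
candidate compounds are most likely to bind. RankVS treats this as a
*ranking* problem, in direct analogy to web search: the target is the
query, the compounds are the documents, and the goal is a scoring function
`f(target, compound)` whose induced ordering puts strong binders first.
Framing screening as learning-to-rank rather than regression has two
practical payoffs:

1. **Novel targets.** Because the score is a function of a joint
   target-compound feature vector, a model trained on *other* targets can
   rank compounds for a target with no affinity data of its own.
2. **Heterogeneous data.** Pair-wise rankers consume ordered compound
   pairs formed *within one target only*. Any strictly increasing
   transformation of a target's labels leaves its pair set unchanged, so
   targets measured on different platforms (pIC50 for one, pKi for
   another) can be pooled without converting between scales.

## Labels: five-grade affinity relevance

Affinities on the negative log10 molar scale are discretized with
`gradeAffinity()`: grade 0 below 6, then one grade per unit, grade 4 at 9
and above; intervals are left-closed so a boundary value takes the higher
grade. Grade 1 starts exactly at the conventional 1-micromolar activity
cutoff (`labelActive()`, value >= 6), so "active" coincides with "grade at
least 1". pKi and pKd are graded with the same thresholds as pIC50: all
three live on the same -log10 molar scale and the grades are only ever
compared within one target anyway. A target mixing measurement types is
rejected by `harmonizeLabels()` because its within-target ordering would
be ill-defined.

`applyCurationFilters()` mirrors common benchmark-curation practice:
duplicate (target, compound) records collapse to the first occurrence;
targets whose ligands cover only grades {0, 1} are dropped, as are targets
whose highest observed grade holds under 5% of records; an optional window
on the per-target ligand count can be supplied but none is enforced by
default (public-database ligand counts vary too much for one window to be
canonical).

## Features

**Targets** are featurized from sequence alone with the CTD descriptor
(`ctdFeatures()`): 7 physicochemical properties, each splitting the 20
canonical residues into 3 groups; per property 3 Composition, 3 Transition
and 15 Distribution statistics, giving 7 x 21 = 147 values. The grouping
tables ship as a plain CSV (`inst/extdata/ctd_property_groups.csv`) so the
mapping is auditable. The Distribution percentile index for a group with N
occurrences is `max(1, ceiling(p * N))` — the conventional definition.
Non-canonical residues are rejected by default (the property groups are
defined only for the 20 canonical letters), with an opt-in surrogate
mapping.

**Compounds** are fixed-length 32-vectors. Precomputed vectors pass
through unchanged; when only SMILES are available, a built-in open
descriptor set (via ChemmineR/ChemmineOB) covers polar surface area, logP,
molar refractivity and Gasteiger partial-charge statistics, padded with
constitutional counts to 32. Commercial descriptor sets of the same width
can be supplied as precomputed tables; nothing downstream depends on which
32-vector is used.

**Pair mappings.** Two feature functions turn (target, compound) into one
vector:

* `mapConcat()` — side-by-side concatenation, 147 + 32 = 179 entries. A
  linear scorer on this representation decomposes into a target-only term
  (constant within a query, irrelevant to ranking) plus a *single global*
  compound preference: it cannot express target-specific preferences.
* `mapCrossTerm()` — the Kronecker product, 147 x 32 = 4704 entries in
  target-major order. A linear scorer here is exactly a bilinear form
  `t' W c`, i.e. a compound preference that varies linearly with the
  target's features. This is the mechanism by which one linear model
  serves many targets.

Feature matrices are standardized by default (`standardizeFeatures()`,
population standard deviation, zero-variance columns mapped to 0), always
fitted on training rows and re-applied verbatim to test rows. For the
cross-term representation this matters empirically: without column
scaling, high-variance CTD blocks dominate the margin and cross-target
transfer degrades badly.

## Evaluation: NDCG@k

`dcgAtK()` implements the exponential-gain discounted cumulative gain
`sum_r (2^y(r) - 1) / log2(1 + r)` over the top k positions;
`ndcgAtK()` divides by the DCG of the descending-grade ideal ordering, so
a perfect ranking scores exactly 1. Two deliberate conventions:

* ties in predicted scores are broken by compound id (stable,
  reproducible — reported numbers never depend on sort internals);
* an all-zero-grade query has ideal DCG 0 and is scored 0, not NaN and
  not 1: a query with no ranking signal should not inflate averages.

Integer grades (0-4), not raw affinities, are the gains: the exponential
gain is meant for small relevance integers. The default depth is k = 10 —
ranking quality at the top of the list is what matters when only a
handful of candidates proceed to assay.

## The seven rankers

All fitters consume a list of `RankingGroup` objects (one per target) and
return a `RankerModel` scoring via `scoreFeatures()`. Pair-based methods
build ordered pairs strictly within queries (`enumeratePairs()`).

* **PRank** (point-wise): ordinal perceptron with a shared weight vector
  and K-1 monotone thresholds; the update provably keeps thresholds
  sorted (asserted in the tests along the whole trajectory).
* **RankNet** (pair-wise): preference probability
  `sigmoid(f(x_i) - f(x_j))` with cross-entropy loss; linear scorer by
  default, optional one-hidden-layer sigmoid network. Full-batch gradient
  descent with step halving, so the training loss is non-increasing by
  construction.
* **RankBoost** (pair-wise): boosting over a distribution on pairs; weak
  rankers are single-feature thresholds at midpoints of distinct sorted
  values, selected each round by maximizing the weighted pair agreement
  r via prefix sums; `alpha = 0.5 log((1+r)/(1-r))` with r clipped to
  +/-(1 - 1e-10) so a perfect weak ranker cannot yield an infinite
  weight.
* **Ranking SVM** (pair-wise): hinge-loss L2 maximum margin on pair
  difference vectors through the origin. Solved exactly by dual
  coordinate descent (compiled, seeded sweep order); for linear kernels
  this is the same direction as the dedicated cutting-plane solvers.
* **AdaRank** (list-wise): boosting over *queries* with NDCG@k itself as
  the round criterion; weak rankers are single raw features.
* **ListNet** (list-wise): top-one softmax distributions over grades vs
  scores, cross-entropy loss, linear scorer, step-halved gradient
  descent. The target distribution uses `exp(grade)` — the canonical
  increasing map.
* **SVR baseline**: epsilon-SVR on pooled (feature, grade) instances,
  delegated to e1071/libsvm; support vectors are retained so scoring is
  self-contained and JSON-serializable like every other model. Grades
  (not raw affinities) are regressed, for consistency with the rankers.

Defaults (learning rate 0.01, 200 epochs, C = 1, 100 boosting rounds, 20
dual-CD sweeps) are ordinary textbook settings, configurable per
algorithm. All fits are deterministic given data and seed; models
round-trip through full-precision JSON with identical scores.

## Experiment strategies

Four seeded runners cover the scenarios the framework is meant for. All
of them split each target's compounds with the same per-target,
grade-stratified, seeded fold assignment (`stratifiedFolds()`; the RNG
substream is keyed by target id, so a target's folds do not depend on
which other targets are present). That makes test partitions identical
across strategies at equal seed — the comparisons are paired by design.

1. **Within-target CV** (`runStrategyWithinTarget`): the classical
   single-target setting; per target, k-fold CV per algorithm,
   fold-averaged NDCG@k.
2. **Leave-one-target-out** (`runStrategyLeaveOneOut`): train on all
   other targets, evaluate on the held-out target's folds — the
   novel-target scenario. One model per held-out target.
3. **Family-restricted** (`runStrategyFamily`): as 2, but training is
   restricted to the held-out target's protein family, probing whether
   phylogenetic relatedness makes better teachers.
4. **Heterogeneous integration** (`runStrategyHeterogeneous`): targets
   measured on different platforms are harmonized per target and pooled;
   the ranking SVM is trained once per held-out target under each of the
   two pair mappings, and both numbers are reported.

The headline number is the macro (fold-then-target) average; per-fold
values stay in the report, so the alternative pooling is a one-liner.
Every runner records an audit trail of train/test membership; the test
suite asserts, by set intersection, that no test instance ever appears in
its own training set. Reports are written as CSV (6 significant digits)
plus full-precision JSON, with a manifest (command, config, seed, package
version, input digests).

## The synthetic benchmark

Real curated benchmarks cannot ship with a package, so `genBenchmark()`
generates one with the statistical structure the method assumes, from a
single master seed via fixed substreams (sequences, latents, interaction
matrix, noise each draw from their own derived seed).

* **Targets.** Each family has a Dirichlet(2)-drawn residue-frequency
  profile and a template sequence sampled from it (length 120-400);
  members are template copies with each position resampled from the
  family profile with probability 0.15. Families therefore carry distinct
  compositional signatures while members stay similar — the
  low-dimensional across-target structure that makes cross-target
  learning possible at all, as in real protein families. A mutation rate
  of 0.15 keeps members recognizably related (roughly the divergence of
  close homologs) without collapsing them into duplicates.
* **Compounds.** 32-dim descriptors as independent standard normals, one
  block per target; optional toy SMILES for I/O tests.
* **Affinities.** The latent affinity is the bilinear form
  `a = l_t' M_t c + noise`, with `M_t = f M_shared + (1-f) M_own`
  blending a shared and a target-specific interaction matrix
  (`sharedModelFraction` f = 1: one shared pharmacology; f = 0:
  unrelated targets, the regime where cross-target transfer must fail).
  Default noise is 0.3 grading units. Per target, affinities are affinely
  rescaled onto [4.25, 10.75] so all five grades are populated; if the
  affine map leaves a grade empty, an equally-spaced rank-based monotone
  map is used instead — it changes nothing the ranking labels encode,
  which is the within-target order. Constant affinity vectors are left
  constant (with a coverage warning) rather than having an artificial
  order imposed.
* **Latents.** By default (`latentSource = "family"`) latents are drawn
  around per-family centers and are *not* recoverable from sequence —
  the honest hard setting. With `latentSource = "ctd"` the latents are
  the centered Composition block of the observable CTD vector, making the
  affinity exactly bilinear in (CTD, descriptor): a linear scorer under
  the cross-term mapping can represent the truth exactly, which is the
  configuration used for recovery tests. The Composition block is used
  because it is the CTD component that is stable within a family but
  distinct between families; with 21 such coordinates and 23 training
  targets, the relevant target subspace is fully spanned in
  leave-one-target-out training, so recovery failures indicate estimator
  problems rather than an unlearnable generator.

**What passing synthetic tests does and does not show.** The generator
reproduces the *structural* premises (query-grouped graded labels,
bilinear target-compound interactions, family structure, platform
heterogeneity) but not real chemical-space geometry, assay noise
distributions, or binding physics. Results on it validate the
implementation and the relative behavior of mappings and strategies; they
say nothing quantitative about screening performance on real libraries.

## Problem sizes and numerical choices

The test suite exercises the pipeline at 24 targets x 40 compounds for
the full leave-one-target-out recovery study (noise-free, shared model,
cross-term mean NDCG@10 at or above 0.95) and at 8 targets x 25 compounds
across 20 seeds for the paired mapping comparison — sizes chosen so the
whole study re-runs from scratch in a few minutes on one CPU while
keeping 23-target training pools, enough to span the 21-dimensional
latent space. Other choices worth stating once: population (not sample)
standard deviation in standardization; zero-variance columns transform to
0; the dual-CD solver stops when the largest multiplier change in a sweep
falls below 1e-4; single-item queries contribute no ListNet gradient and
are skipped with a message; RankBoost stops early when no weak ranker
achieves positive weighted agreement.

## Known limitations

* The built-in 32-descriptor set is an open stand-in with the same
  contract as commercial general-descriptor sets, not a reimplementation
  of any of them; absolute values differ between descriptor providers.
* Hidden-layer RankNet is a minimal full-batch implementation — adequate
  for the package's scale, not a deep-learning framework.
* No hyperparameter search is built in; defaults are documented and
  configurable, and the strategies compare algorithms under equal
  conditions rather than at per-algorithm optima.
* Family annotations are user-supplied (or generated); no phylogenetic
  inference is performed.
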