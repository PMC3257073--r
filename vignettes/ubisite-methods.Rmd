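---
title: "Methods: feature-subset ensembles for lysine ubiquitylation site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature-subset ensembles for lysine ubiquitylation site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Ubiquitylation marks substrate lysines, and only a minority of a
proteome's lysines are modified, so the prediction task is binary
classification of lysine-centered sequence windows under class imbalance
(the curated data this package is modeled on had roughly 300 positive and
560 negative sites, about 1:1.9). The predictor has three stages.

**Encoding.** A window of `w = 21` residues around each lysine (padding
with the inert letter 'X' at sequence ends) is mapped to 627 named
features: 86 grouped amino-acid composition features, 420 PSSM
conservation scores, 100 Atchley-factor values and 21 disorder scores.
Every coordinate is registered (`feature_registry()`) with its family and
window site so that downstream selections can be audited.

**Feature selection.** Features are discretized into at most `B = 5`
equal-frequency bins and screened greedily. The criterion for a candidate
$f$ given the selected set $FS$ and class $C$ is

$$J'(f) = \min_{f_s \in FS} \frac{I(f;C \mid f_s)}{H(f,C)},$$

the smallest amount of class information $f$ adds beyond any single
already-selected feature, normalized by the joint entropy of the
candidate and the class. The minimum over single conditioning features
replaces conditioning on all of $FS$ because high-dimensional plug-in
estimates are unreliable at these sample sizes; the normalization removes
the bias of raw conditional MI toward features with many distinct values.
Candidates whose criterion is (numerically) zero duplicate selected
information and are pruned permanently. Running the selector from $P$
consecutive starting ranks of the marginal-MI ordering yields $P$
overlapping subsets that view the signal from different anchors.

**Classification.** One random forest is trained per subset, on that
subset's columns only; the ensemble predicts by majority voting over the
members' class votes, with ties labeled positive.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `w` | 21 | window size (residues); 10 flanks on each side of the lysine, the size established for this task |
| `B` | 5 | equal-frequency bins per feature for all information estimates; robust to skewed feature distributions |
| `k` | 12 | maximum subset size; on the original data the criterion flattened after 12 features |
| `delta` | 0.015 | stop when successive criterion values differ by less than this — the next feature adds essentially nothing new |
| `epsilon` | 1e-12 | numerical zero for the pruning rule (plug-in estimates are rarely exactly 0) |
| `P` | 10 | number of subsets / starting ranks |
| `Qbc` | 10 | base classifiers in the voting ensemble |
| `n_trees` | 500 | trees per forest; `mtry` defaults to `floor(sqrt(d))` of the member's subset size |

No class re-weighting is applied anywhere; imbalance is addressed at the
reporting level by MCC and the tie-positive voting rule, which favors
sensitivity on the minority class.

## Algorithmic choices that were genuinely open

* **Seeding and the stopping rule.** The trajectory of a subset records
  the seed's normalized marginal MI, $I(f;C)/H(f,C)$, followed by the
  $J'$ value of each greedy pick. The `delta` rule compares successive
  greedy $J'$ values only: the seed entry is not a $J'$ quantity, so the
  first greedy pick is always accepted, and the pick that falls within
  `delta` of its predecessor is rejected (selection ends there). Both `k`
  and `delta` are active; whichever triggers first stops the subset.
* **Starting points.** Multiple subsets are obtained by seeding at
  consecutive ranks $t = 0, \dots, P-1$ of the marginal-MI ordering. This
  is the minimal deterministic reading of "different starting points";
  the original description fixes $t = 0$ for a single subset and leaves
  the multi-subset seeding unspecified.
* **Ties.** All ranking and selection ties break toward the smaller
  registry index, making every selection path deterministic.
* **Dipeptide alphabet.** The 121 ordered dipeptides are counted on the
  11-group alphabet ($11^2 = 121$) and merged to 66 unordered categories;
  counting on raw amino acids would give $20^2 = 400$, inconsistent with
  the published feature counts.
* **Factor block.** The Atchley block covers the 20 *flanking* sites and
  excludes the invariant central lysine: $20 \times 5 = 100$ is the only
  reading consistent with the printed count, since the window has 21
  sites. The center's conservation still enters through the PSSM block.
* **Window site indexing.** Sites are numbered 1..21 with the lysine at
  site 11 throughout. (Published site-specific analyses of this design
  are ambiguous about whether the center is site 11 or 13; this package
  pins the convention and all provenance tables use it.)
* **PSSM normalization scope.** Min-max over the whole per-protein
  matrix, the simplest reading of "normalize the values of the PSSM"; a
  constant matrix maps to 0.5 with a warning. Normalization is idempotent
  and range-bounded, which the tests assert.
* **Selection inside folds.** By default, discretization and subset
  selection re-run inside every cross-validation training fold. A
  `select_once` flag reproduces the historical select-once-then-validate
  protocol and warns about the feature-selection leakage it introduces.
* **MCC degenerate rule.** Any zero factor in the MCC denominator yields
  MCC = 0; a zero Sn/Sp denominator yields NA. Reported Sn/Sp/AC are
  percentages.

## The synthetic benchmark

`generate_dataset()` emulates the *structure* of the curated data — 60
proteins of 200–320 residues, lysine density 0.055 (≈ 860 sites), 35%
positives (imbalance ≈ 1:1.9) — with a known generative signal:

* a flanking **motif** at offsets −2, −1, +1, +2, +3 whose preferred
  residues overwrite positive-site flanks with probability
  `motif_strength` (default 0.9, a strong motif);
* surrogate **PSSMs**: integer background log-odds N(0, 2) plus a direct
  class-conditional shift (`pssm_shift * motif_strength`, default
  8 × 0.9) at the motif cells of positive sites, plus N(0, 1) noise,
  then min-max normalized exactly like parsed PSSMs;
* **disorder tracks**: smoothed uniform noise in [0.05, 0.55] plus a bump
  (`disorder_bump * motif_strength`, default 0.4 × 0.9) with squared
  triangular decay over ±3 residues of positive sites, clamped to [0,1].

Both planted effects scale with `motif_strength`, so strength 0 is an
exact null: features are class-independent by construction, and the
pipeline's cross-validated MCC on such data (or on label-permuted data
via `make_null_permutation()`) hovers at 0.

**Ground truth.** `truth$informative_ids` lists the *primary* planted
features: the five PSSM cells receiving the direct shift and the
center-site disorder feature where the bump peaks. The generator plants
these as the strongest class signals on purpose; residue-mediated echoes
of the same information (Atchley factors and compositions of rewritten
flanks, off-center disorder sites) are excluded from the ground truth
because a redundancy-eliminating selector is *supposed* to skip features
that duplicate what it already selected, so crediting or penalizing echo
recovery would measure the wrong thing.

**What passing tests do and do not show.** The synthetic data have
independent windows given the planted signal, uniform background
composition, and surrogate (not alignment-derived) PSSMs. Success here
demonstrates that the estimators, the selector, the ensemble and the
protocols are implemented correctly and can recover a planted signal
under realistic dimensionality and imbalance. It does not certify
accuracy on real proteomes, where motifs are weak and context-dependent,
homology correlates windows, and PSSM/disorder tracks carry their own
biases; the historical headline accuracies (≈ 77–79%) depended on
curated Swiss-Prot data and NR-database profiles that are not bundled.

## Numerical and degenerate-input conventions

All information quantities are plug-in estimates in bits (log base 2).
Equal-frequency bin edges come from type-7 sample quantiles; duplicated
edges merge bins, constant features occupy a single bin, and a
two-valued feature keeps its two codes. Empty windows, non-lysine
centers, even window sizes, misaligned PSSMs and all-zero confusion
tables raise errors; padded positions are inert in every encoder
(excluded from composition denominators and dipeptide pair counts, zero
factor/PSSM/disorder contributions).

## Problem sizes used by the test suite

The acceptance-style experiments run the full default study conditions:
selector recovery on 20 independent datasets, and cross-validated
discrimination plus label-permuted null on 10 datasets with the complete
pipeline (selection inside folds, 10 members × 500 trees). Unit tests use
smaller generators (3–10 proteins, 2–3 subsets, 30–100 trees), chosen as
the smallest sizes at which the tested property is non-trivial.

## Known limitations

* Plug-in MI estimates are biased upward at small sample sizes; the
  selector compares features under a common bias rather than correcting
  it, and `epsilon` exists because estimates are rarely exactly zero.
* `criterion_J` conditions on one selected feature at a time (by
  design); genuine three-way interactions are invisible to it.
* The mRMR baseline shares the discretization and tie rules but not the
  normalization, so its scores are not comparable across feature
  cardinalities in the way $J'$ is.
* Disorder and PSSM providers are file-based; running VSL2-style
  predictors or PSI-BLAST itself is out of scope, as is homology
  reduction of input protein sets (inputs are assumed pre-filtered).
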