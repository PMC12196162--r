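---
title: "Screening for senolytics with an imbalance-aware dual predictor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for senolytics with an imbalance-aware dual predictor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Senolytic discovery is an extreme small-data problem: on the order of a
hundred validated actives — mechanistically heterogeneous ones, from kinase
inhibitors to cardiac glycosides — against thousands of inactives, screened
against libraries of tens of thousands of molecules. This vignette explains
the model choices senoscreen makes for that regime, the knobs that matter,
what the synthetic benchmark does and does not establish, and the numerical
conventions the implementation commits to.

## The pipeline and its assumptions

The pipeline is target-agnostic: it learns directly from phenotypic labels,
assuming only that senolytic activity is partially predictable from
molecular structure. Its stages are

1. **curation** — canonicalize, deduplicate, and remove every negative whose
   maximum ECFP (2048-bit, radius-2) Tanimoto similarity to any positive
   exceeds 0.9;
2. **featurization** — dense molecular embeddings by default, fingerprints
   and descriptors as alternatives;
3. **minority oversampling** by stochastic re-embedding;
4. **dual model** — RBF SVM plus a small neural-network ensemble;
5. **screening** — applicability-domain-gated consensus calls with novelty
   annotation and source enrichment.

The negative filter encodes the belief that the inactive pool may contain
unrecognized actives: anything nearly identical to a known active is too
risky to teach the model as "inactive". The cut is strict (`> 0.9`), so a
pair at exactly 0.9 is kept. Conflicts between the tables resolve
positive-wins, for the same reason.

## Oversampling by re-embedding

Chemical language models produce slightly different embeddings for the same
molecule across batches when not seeded. Embedding each training active in
`k = 5` independent batches therefore yields five *real* feature vectors per
active — unlike SMOTE-style interpolation, no synthetic molecule is
invented. With 111 actives this produces the canonical 555-row positive
block.

Two protocols are implemented because their difference is scientifically
important:

* `leakage_safe` (default): split first, augment the training side only.
* `augment_first`: augment the full dataset, then split rows. Replicates of
  a test active then sit in the training set; test recall rises toward 1.0.
  The mode exists to study exactly that effect (the test suite shows
  `augment_first ≥ leakage_safe ≥ none` for recall on the benchmark) and
  is loudly labelled — it must not be used for honest evaluation.

A consequence for **model selection**: once the training matrix contains
replicate rows of the same compound, row-level cross-validation is itself
leaky — replicates of one compound land on both sides of every fold, and
the winner is whatever configuration memorises best. `grid_search()`
therefore accepts a `groups` argument (compound ids) that assigns folds per
compound, and a `selection` argument (`"f1"` default, `"auc"` available, the
other metric as tiebreak). The recovery benchmark in the test suite tunes
the SVM kernel width exactly this way.

## The two models

* **SVM**: RBF kernel, `C = 20`, balanced class weights
  (`n / (2 n_c)`), signed decision score, predicted label `score > 0`.
  `gamma` defaults to `1/d` and is the one knob worth tuning per feature
  space (see above). Inputs are used unscaled; embeddings are already on a
  common scale.
* **MLP**: exactly one hidden layer (default width 256 — the width is not
  fixed by the protocol, and the grid search can tune it), ReLU, inverted
  dropout 0.5, full-batch Adam at learning rate 1e-4, cross-entropy loss,
  at most 3000 epochs. Early stopping monitors the *training* loss (no
  validation split is prescribed) with patience 100 and restores the best
  weights. Ten sub-models differing only in seed are averaged; averaging
  provably cannot increase the across-seed variance, and the test suite
  checks it empirically.

The network is implemented in the package (plain matrix algebra with a
seeded RNG) so that training is bit-reproducible under a fixed seed — the
configuration above is part of the method, and reproducibility of every
stage from one master seed is a design requirement.

Consensus is the conjunction of the two strict thresholds
(`SVM > 0`, `MLP > 0.5`); a score exactly at a threshold is negative. Hits
are ranked by the raw sum `svm_score + mlp_prob`. The sum mixes a margin
(unbounded) with a probability (bounded); that is the established reporting
convention this package follows, and a min-max-normalized variant is
available behind `normalized_rank = TRUE` for users who prefer commensurate
scales.

## Applicability domain

`ADT = D + Zσ` with `D`, `σ` the mean and standard deviation of all
pairwise Euclidean distances among training rows. Conventions the
implementation fixes explicitly:

* unordered pairs, self-distances excluded;
* `σ` uses the population (divide-by-N) form;
* a query is inside iff its nearest-neighbour distance is *strictly* below
  ADT — membership is monotone in `Z`;
* distances live in the same feature space the deployed models consume
  (embeddings by default), and the reference matrix holds one unaugmented
  row per training compound;
* out-of-domain compounds are flagged `in_ad = FALSE` but never dropped:
  the domain is a reliability annotation, not a filter.

`Z = 0.5` is the conventional default width.

## Enrichment

For each source (herb, target, pathway — any compound-to-category mapping):
`p = P(X ≥ k)` for `X ~ Hypergeometric(N, K, n)`, BH-adjusted across
sources, significance at `p_adj < 0.05`. The universe defaults to the
compounds carrying at least one annotation (the convention of the standard
enrichment tools); an explicit universe is available because the choice
genuinely changes `N`. No source-size filter is applied by default —
medicinal-herb annotations legitimately contain sources with three
compounds, which a transcriptomics-style minimum would silently discard.

## The synthetic benchmark: what it shows and what it cannot

`generate_library()` plants the signal the pipeline assumes: actives are
light decorations (ten one- or two-atom substituents at two ring positions)
of four large fused-ring cores — carbazole, acridine, dibenzofuran,
xanthone, each carrying a fixed bulky side chain. Because the shared core
dominates the circular-fingerprint bit set, two actives of one scaffold
always keep Tanimoto similarity above 0.5: planted actives are recoverable
by design. Negatives come from twelve small disjoint scaffolds with a wider
substituent alphabet (~5000 unique structures). Difficulty is controlled by
two dials, not by feature geometry:

* `scaffold_overlap` — the fraction of negatives drawn from the active
  grammar (structurally active-like inactives, the hard part of screening);
* `label_noise` — random label flips.

The mock embedder completes the loop: a molecule's base vector is a seeded
Gaussian random projection of its ECFP on-bits (scaled by `1/sqrt(bits)`),
so structural similarity translates into embedding proximity, and each
unseeded batch adds `N(0, τ²I)` noise (`τ = 0.1` by default, small against
unit-scale coordinates; `τ = 0` gives a fully deterministic embedder). The
displacement law between two unseeded batches, mean squared distance
`2·dim·τ²`, is verified in the tests.

The default benchmark (50 actives, 1000 inactives, 5% overlap, 2% noise)
is evaluated against the *planted* labels. That choice matters: at 20:1
imbalance, 2% symmetric flips make roughly a quarter of the observed
positives structurally negative, capping observed-label AUC far below what
any model can honestly reach — recovery of the planted signal is the
meaningful question, and both models exceed held-out AUC 0.95 on it while
every held-out planted active finds a training active above similarity 0.5.

What passing these tests does **not** show: the fixtures have no chemical
realism (no ADMET, no drug-likeness, no stereochemistry, no activity
cliffs), actives cluster far more cleanly than literature-curated
senolytics do, and the mock embedder's noise is isotropic where a real
pretrained embedder's batch variability is not. Results on the benchmark
bound the pipeline's correctness, not its real-world accuracy.

## Numerical choices and degenerate inputs

* Tanimoto of two empty fingerprints is 0/0: defined as 0 with a warning —
  conservative for novelty screening (an empty query matches nothing).
* Metrics with zero denominators (precision with no positive predictions,
  etc.) are reported as 0 and listed in a `degenerate` field rather than as
  NaN, so averaged cross-validation reports stay finite; AUC on a
  single-class truth vector is NA with a flag.
* The precision-recall area uses the step-wise average-precision sum, which
  avoids the optimism of trapezoidal PR interpolation; the bootstrap
  percentile CI redraws any resample that lost a class.
* Lifespan extension rates (a reporting utility for whole-organism assays)
  are `100 × (treated − control)/control`, rounded half away from zero to
  one decimal.
* Non-finite descriptor values are flagged and returned as NA, never
  silently dropped; unparseable SMILES raise a structured error carrying
  the offending strings.
* Novelty ties break on the lexicographically smallest active id; screening
  output ties break on compound id. All orderings are deterministic.

## Problem sizes used by the shipped tests

The suite scales the study down so it runs comfortably on one CPU:
embeddings at width 32-128 (the contract default is 768), networks of 32-64
hidden units trained for up to 150 epochs at learning rate 0.01, ensembles
of 2-3 sub-models, and the benchmark above at 1050 compounds. These choices
are recorded here as the package's own test design; all method defaults
remain the full-size configuration.

## Known limitations

* No pretrained chemical language model is bundled; real embedders plug in
  through `embedder()` / `register_embedder()`.
* FP2 fingerprints require the optional Open Babel backend; core
  functionality never depends on it.
* The MLP is full-batch and CPU-bound — appropriate for thousands of
  compounds, not millions.
* Enrichment mechanics generalise to targets and pathways, but no pathway
  database ships with the package.
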