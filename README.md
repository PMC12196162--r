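# senoscreen

Virtual screening for **senolytics** — compounds that selectively kill
senescent cells — from small, heavily imbalanced training sets. Known
senolytics number in the low hundreds while screening libraries hold tens of
thousands of molecules, so the package is built around the statistical
problems that regime creates: protecting the negative class from hidden
actives, oversampling the minority class without fabricating molecules,
gating predictions by an applicability domain, and demanding consensus
between two independent models before calling a hit.

It is aimed at computational chemists and drug-repurposing groups who have
(1) a labelled table of active/inactive compounds as SMILES, (2) one or more
unlabelled libraries to screen, and optionally (3) compound-to-source
annotations (e.g. medicinal herbs) for enrichment analysis.

## The method

**Curation.** Positive and negative compound tables are canonicalized and
merged (a structure appearing in both is kept as positive — the negative
pool is assumed to harbour rare undetected actives). Every negative with
max Tanimoto similarity above 0.9 to any positive — on ECFP fingerprints,
2048 bits, radius 2 — is removed:

    T(A, B) = |A ∩ B| / |A ∪ B|,   drop negative j if max_i T(F_j, F_i⁺) > 0.9

**Features.** Molecules can be represented as ECFP bit vectors, a frozen
200-descriptor vector, 1024-bit FP2 (optional Open Babel backend), or dense
embeddings behind a pluggable *embedder contract*. Embeddings are the
default predictor input. A chemical-language-model embedder is stochastic
across batches; the package ships a mock embedder with the same contract
(`base(molecule) + N(0, τ²I)` per batch) for offline work.

**Oversampling.** Each training positive is embedded `k = 5` times in
independent unseeded batches, giving `k` distinct but intrinsically similar
feature rows per active (555 rows from 111 actives) — minority oversampling
with real molecules instead of interpolated ones. The default
`leakage_safe` mode augments only the training partition;
`augment_first` reproduces the augment-then-split protocol whose replicate
leakage inflates test recall.

**Dual predictor.** An RBF support-vector machine (`C = 20`, balanced class
weights) exposing a signed decision score, and an ensemble of 10
single-hidden-layer networks (Adam, learning rate 1e-4, dropout 0.5, up to
3000 epochs with early-stopping patience 100) whose probabilities are
averaged. A library compound is a hit only when **both** models agree:
`SVM score > 0 AND MLP probability > 0.5`. Hits are ranked by the score sum.

**Applicability domain.** With `D` and `σ` the mean and standard deviation
of all pairwise Euclidean training distances, a query is inside the domain
iff its nearest-neighbour distance is below `ADT = D + Zσ` (default
`Z = 0.5`). Out-of-domain compounds are flagged, not dropped.

**Novelty and enrichment.** Every hit is annotated with its maximum
Tanimoto similarity to the training actives (`match_degree`; below 0.3-0.5
marks structurally novel chemistry), and hit sets are tested for source
(herb) enrichment with the hypergeometric upper tail
`p = P(X ≥ k), X ~ Hypergeom(N, K, n)` and Benjamini-Hochberg correction.

## Worked example

Everything below is synthetic and runs offline in under a minute:

```r
library(senoscreen)

# a labelled library with planted active scaffolds, 10:1 imbalance,
# 5% scaffold overlap in the negatives and 2% label noise
lib <- generate_library(n_pos = 40, n_neg = 400, scaffold_overlap = 0.05,
                        label_noise = 0.02, seed = 7)
ds <- assemble_dataset(lib[lib$label == 1, c("id", "smiles")],
                       lib[lib$label == 0, c("id", "smiles")])
ds <- filter_negatives(ds, threshold = 0.9)
#> <curated_dataset> 440 compounds (48 positive / 392 negative), 0 curation log entries

emb <- mock_embedder(dim = 128, tau = 0.1, base_seed = 1)
pred <- train_predictor(ds, emb, k = 5,
                        mlp_cfg = mlp_config(hidden_width = 64,
                                             learning_rate = 0.01,
                                             max_epochs = 150, patience = 30),
                        n_sub = 3, seed = 11)
#> <seno_predictor> trained on 48 actives / 392 inactives (k=5, ensemble of 3, embedder=mock)

query <- generate_library(n_pos = 10, n_neg = 90, scaffold_overlap = 0.05,
                          seed = 99)
query$id <- sub("CPD", "QRY", query$id)
records <- screen_library(pred, query[, c("id", "smiles")])
head(records[, c("id", "svm_score", "mlp_prob", "consensus",
                 "in_ad", "match_degree", "match_id")], 5)
#>         id svm_score mlp_prob consensus in_ad match_degree match_id
#> 1 QRY00006     1.536    1.000         1  TRUE        0.787 CPD00006
#> 2 QRY00005     1.513    1.000         1  TRUE        0.755 CPD00006
#> 3 QRY00013     1.454    1.000         1  TRUE        0.787 CPD00008
#> 4 QRY00003     1.176    1.000         1  TRUE        1.000 CPD00009
#> 5 QRY00012     0.932    0.997         1  TRUE        1.000 CPD00031
sum(records$consensus)
#> 10
```

The top records read like a screening report: `QRY00006` passes both
models (SVM score 1.54 > 0, MLP probability 1.00 > 0.5), lies inside the
applicability domain, and its closest training active (`CPD00006`) has
Tanimoto similarity 0.787 — an analogue of a known active rather than novel
chemistry, whereas records with `match_degree` below 0.5 would be the
structurally novel leads.

Source enrichment over the ten consensus hits recovers a planted herb:

```r
map <- generate_source_map(query$id, n_sources = 12,
                           planted = list(source = "Herb_planted",
                                          members = query$id[query$label == 1]),
                           seed = 3)
enr <- enrich_sources(records$id[records$consensus == 1], map)
head(enr[, c("source", "k", "K", "p", "p_adj", "enriched")], 3)
#>         source k  K        p    p_adj enriched
#> 1 Herb_planted 6 10 3.18e-05 0.000414     TRUE
#> 2      Herb012 1  5 4.16e-01 1.000000    FALSE
#> 3      Herb007 1  7 5.33e-01 1.000000    FALSE
```

A thin command-line front end over the same functions lives at
`inst/cli/senoscreen.R` (`simulate`, `featurize`, `curate`, `train`,
`screen`, `enrich`); run any subcommand with `--help`.

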