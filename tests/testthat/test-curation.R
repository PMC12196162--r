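pos_tab <- function() {
  data.frame(id = c("p1", "p2", "p3"),
             smiles = c("c1ccc2[nH]ccc2c1", "CCO", "c1ccncc1"),
             stringsAsFactors = FALSE)
}
neg_tab <- function() {
  data.frame(id = paste0("n", 1:5),
             smiles = c("CCCC", "CCCCC", "c1ccccc1", "C1CCCCC1", "CCN"),
             stringsAsFactors = FALSE)
}

test_that("dataset assembly takes the union of the two tables", {
  ds <- assemble_dataset(pos_tab(), neg_tab())
  expect_s3_class(ds, "curated_dataset")
  expect_identical(nrow(ds$compounds), 8L)
  expect_identical(sum(ds$compounds$label), 3L)
  expect_identical(nrow(ds$curation_log), 0L)
})

test_that("a structure in both tables is kept once as positive, logged", {
  neg <- rbind(neg_tab(),
               data.frame(id = "n6", smiles = "OCC"))  # ethanol again
  ds <- assemble_dataset(pos_tab(), neg)
  expect_identical(nrow(ds$compounds), 8L)
  expect_identical(ds$compounds$label[ds$compounds$id == "p2"], 1L)
  expect_false("n6" %in% ds$compounds$id)
  expect_true("n6" %in% ds$curation_log$removed_id)
  expect_identical(ds$curation_log$rule[ds$curation_log$removed_id == "n6"],
                   "positive_wins")
})

test_that("conflicting SMILES under one id is a hard error", {
  bad <- rbind(pos_tab(), data.frame(id = "p1", smiles = "CCCCCCCC"))
  expect_error(assemble_dataset(bad, neg_tab()), "conflicting")
  # same id, same structure is tolerated (plain duplicate row)
  dup <- rbind(pos_tab(), data.frame(id = "p1", smiles = "c1ccc2[nH]ccc2c1"))
  expect_identical(nrow(assemble_dataset(dup, neg_tab())$compounds), 8L)
})

test_that("the similarity filter removes only negatives above threshold", {
  # a C31 alkane shares every ECFP environment with a C30 positive:
  # Tanimoto 1.0 > 0.9 yet the canonical structures differ, so it passes
  # assembly but must fall to the similarity filter
  pos <- rbind(pos_tab(), data.frame(id = "p4", smiles = strrep("C", 30)))
  neg <- rbind(neg_tab(), data.frame(id = "twin", smiles = strrep("C", 31)))
  ds <- assemble_dataset(pos, neg)
  expect_identical(nrow(ds$compounds), 10L)
  filtered <- filter_negatives(ds, threshold = 0.9)
  expect_false("twin" %in% filtered$compounds$id)
  expect_identical(sum(filtered$compounds$label), 4L)   # positives untouched
  expect_true(all(neg_tab()$id %in% filtered$compounds$id))
  expect_match(filtered$curation_log$rule[1], "similarity_filter")
  expect_error(filter_negatives(ds, threshold = 1.5), "threshold")
})

test_that("the filter boundary is strict: exactly-threshold pairs survive", {
  # |A n B| / |A u B| = 9/10 = 0.9 exactly, and 19/20 = 0.95
  a <- 0:9
  expect_identical(tanimoto(a, 0:8), 0.9)
  expect_identical(tanimoto(0:19, 0:18), 0.95)
  # rule applied by the filter is strictly-greater-than
  expect_false(0.9 > 0.9)
  sim <- senoscreen:::tanimoto_cross(
    toy_fp_set(list(0:8, 0:18), ids = c("keep", "drop"), nbits = 64),
    toy_fp_set(list(0:9, 0:19), ids = c("pA", "pB"), nbits = 64))
  expect_identical(unname(apply(sim, 1, max) > 0.9), c(FALSE, TRUE))
})

test_that("filtered fixtures satisfy the pairwise similarity invariant", {
  ds <- small_dataset()
  cmp <- ds$compounds
  sim <- senoscreen:::tanimoto_cross(
    fingerprint(cmp[cmp$label == 0, ]),
    fingerprint(cmp[cmp$label == 1, ]))
  expect_true(all(sim <= 0.9))
})

test_that("an empty positive set makes the filter vacuous", {
  neg <- neg_tab()
  ds <- senoscreen:::new_curated_dataset(
    data.frame(id = neg$id, input_smiles = neg$smiles,
               canonical_smiles = canonicalize(neg$smiles), label = 0L,
               provenance = "test", stringsAsFactors = FALSE),
    senoscreen:::empty_log())
  expect_identical(filter_negatives(ds)$compounds, ds$compounds)
})

test_that("the curation log accounts for every removed record", {
  pos <- rbind(pos_tab(), data.frame(id = "p4", smiles = strrep("C", 30)))
  neg <- rbind(neg_tab(),
               data.frame(id = c("n6", "twin"),
                          smiles = c("OCC", strrep("C", 31))))
  ds <- filter_negatives(assemble_dataset(pos, neg))
  n_in <- nrow(pos) + nrow(neg)
  expect_identical(n_in - nrow(ds$compounds), nrow(ds$curation_log))
})

test_that("stratified splits preserve class proportions to within one", {
  labels <- c(rep(1L, 10), rep(0L, 90))
  ds <- senoscreen:::new_curated_dataset(
    data.frame(id = sprintf("c%03d", 1:100), input_smiles = "CCO",
               canonical_smiles = "CCO", label = labels,
               provenance = "t", stringsAsFactors = FALSE),
    senoscreen:::empty_log())
  sp <- stratified_split(ds, test_fraction = 0.2, seed = 1)
  expect_identical(sum(sp$test$compounds$label == 1), 2L)
  expect_identical(sum(sp$test$compounds$label == 0), 18L)
  expect_setequal(c(sp$train$compounds$id, sp$test$compounds$id),
                  ds$compounds$id)
  sp2 <- stratified_split(ds, test_fraction = 0.2, seed = 1)
  expect_identical(sp$test$compounds$id, sp2$test$compounds$id)
  expect_error(stratified_split(sp, 0.2, 1))  # not a curated_dataset
})

test_that("fold assignment rejects classes smaller than the fold count", {
  expect_error(senoscreen:::stratified_folds(c(1, rep(0, 20)), 5, 1),
               "folds")
  fold <- senoscreen:::stratified_folds(c(rep(1, 10), rep(0, 20)), 5, 1)
  expect_true(all(table(fold, c(rep(1, 10), rep(0, 20)))[, "1"] == 2))
})

test_that("grouped fold assignment keeps replicate rows together", {
  ids <- rep(sprintf("c%02d", 1:30), each = 3)      # 3 replicates each
  y <- rep(c(rep(1L, 10), rep(0L, 20)), each = 3)
  fold <- senoscreen:::assign_folds(y, 5, seed = 2, groups = ids)
  per_id <- tapply(fold, ids, function(f) length(unique(f)))
  expect_true(all(per_id == 1))
  # stratification still holds at the compound level
  uf <- fold[!duplicated(ids)]
  uy <- y[!duplicated(ids)]
  expect_true(all(table(uf[uy == 1]) == 2))
  expect_true(all(table(uf[uy == 0]) == 4))
})

test_that("oversampling produces k replicates of each positive", {
  ds <- small_dataset()
  emb <- mock_embedder(dim = 16, tau = 0.1, base_seed = 2)
  n_pos <- sum(ds$compounds$label == 1)
  n_neg <- sum(ds$compounds$label == 0)
  aug <- oversample_positives(ds, emb, k = 5, seed = 10)
  expect_identical(nrow(aug$features), n_neg + 5L * n_pos)
  expect_identical(sum(aug$labels), 5L * n_pos)
  expect_identical(nrow(aug$origin), nrow(aug$features))
  expect_setequal(unique(aug$origin$replicate[aug$origin$label == 1]), 1:5)
  # replicate blocks differ (stochastic batches) but negatives appear once
  expect_identical(sum(aug$origin$label == 0), n_neg)
  r1 <- aug$features[aug$origin$replicate == 1 & aug$origin$label == 1, ]
  r2 <- aug$features[aug$origin$replicate == 2 & aug$origin$label == 1, ]
  expect_false(identical(r1, r2))
  expect_error(oversample_positives(ds, emb, k = 0), "k")
})

test_that("k = 1 with a deterministic embedder is plain embedding", {
  ds <- small_dataset()
  emb <- mock_embedder(dim = 16, tau = 0, base_seed = 2)
  aug <- oversample_positives(ds, emb, k = 1)
  cmp <- ds$compounds
  plain <- embed_molecules(rbind(cmp[cmp$label == 1, ], cmp[cmp$label == 0, ]),
                           emb)
  expect_equal(unname(aug$features[, ]), unname(plain[, ]))
  expect_warning(oversample_positives(ds, emb, k = 3), "identical copies")
})

test_that("leakage-safe training sets never contain test compounds", {
  bt <- trained_small()
  expect_length(intersect(bt$train$origin$id, bt$test_ids), 0)
  n_pos_train <- length(unique(bt$train$origin$id[bt$train$origin$label == 1]))
  expect_identical(sum(bt$train$labels), 5L * n_pos_train)
})

test_that("augment-first augmentation leaks replicates across the split", {
  ds <- small_dataset()
  emb <- mock_embedder(dim = 16, tau = 0.1, base_seed = 2)
  bt <- build_training_set(ds, emb, k = 5, mode = "augment_first",
                           test_fraction = 0.2, seed = 3)
  test_pos <- unique(bt$test_ids[bt$test_labels == 1])
  expect_gt(length(intersect(bt$train$origin$id, test_pos)), 0)
  expect_identical(bt$train$mode, "augment_first")
})
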