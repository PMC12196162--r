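# Assembly and curation of the labelled training corpus.

new_curated_dataset <- function(compounds, curation_log) {
  structure(list(compounds = compounds, curation_log = curation_log),
            class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  n <- table(factor(x$compounds$label, levels = c(0, 1)))
  cat("<curated_dataset> ", nrow(x$compounds), " compounds (",
      n[["1"]], " positive / ", n[["0"]], " negative), ",
      nrow(x$curation_log), " curation log entries\n", sep = "")
  invisible(x)
}

log_entry <- function(rule, removed_id, reason) {
  data.frame(rule = rule, removed_id = removed_id, reason = reason,
             stringsAsFactors = FALSE)
}

empty_log <- function() log_entry(character(0), character(0), character(0))

#' Assemble a curated dataset from positive and negative compound tables
#'
#' Canonicalizes and de-duplicates the union of a positive (senolytic) and a
#' negative table. A structure appearing in both tables is kept once with
#' label 1 ("positive wins": the negative pool is assumed to harbour rare
#' undetected actives) and logged. Structural duplicates within a table keep
#' the first record. One id carrying two different structures is a hard
#' error.
#'
#' @param pos_table,neg_table data frames with columns `id`, `smiles` and
#'   optionally `provenance`.
#' @return a `curated_dataset`: `$compounds` (id, input_smiles,
#'   canonical_smiles, label, provenance) and `$curation_log`.
#' @export
assemble_dataset <- function(pos_table, neg_table) {
  prep <- function(tab, label) {
    stopifnot(all(c("id", "smiles") %in% names(tab)))
    if (anyDuplicated(tab$id)) {
      dup <- unique(tab$id[duplicated(tab$id)])
      sub <- tab[tab$id %in% dup, ]
      nsmi <- tapply(sub$smiles, sub$id, function(s) length(unique(s)))
      if (any(nsmi > 1)) {
        stop("duplicate id(s) with conflicting SMILES: ",
             paste(names(nsmi)[nsmi > 1], collapse = ", "), call. = FALSE)
      }
      tab <- tab[!duplicated(tab$id), ]
    }
    mol <- molecules(tab$id, tab$smiles)
    mol$label <- label
    mol$provenance <- if ("provenance" %in% names(tab)) {
      tab$provenance[!duplicated(tab$id)]
    } else {
      "unspecified"
    }
    mol
  }
  pos <- prep(pos_table, 1L)
  neg <- prep(neg_table, 0L)

  clash <- intersect(pos$id, neg$id)
  both <- pos$id[pos$canonical_smiles %in% neg$canonical_smiles]
  if (length(clash)) {
    csm <- vapply(clash, function(i) {
      identical(pos$canonical_smiles[pos$id == i],
                neg$canonical_smiles[neg$id == i])
    }, logical(1))
    if (any(!csm)) {
      stop("duplicate id(s) with conflicting SMILES across tables: ",
           paste(clash[!csm], collapse = ", "), call. = FALSE)
    }
  }

  log <- empty_log()
  drop_neg <- neg$id %in% clash | neg$canonical_smiles %in% pos$canonical_smiles
  if (any(drop_neg)) {
    log <- rbind(log, log_entry("positive_wins", neg$id[drop_neg],
                                "structure also present in positive table"))
    neg <- neg[!drop_neg, ]
  }
  all <- rbind(pos, neg)
  dup <- duplicated(all$canonical_smiles)
  if (any(dup)) {
    log <- rbind(log, log_entry("dedup_structure", all$id[dup],
                                "duplicate canonical structure"))
    all <- all[!dup, ]
  }
  rownames(all) <- NULL
  new_curated_dataset(all, log)
}

#' Filter negatives by structural similarity to the positive class
#'
#' Removes every negative whose maximum Tanimoto similarity (ECFP, 2048
#' bits, radius 2 by default) to any positive is strictly greater than
#' `threshold`. Positives are never touched; a negative at exactly the
#' threshold is kept.
#'
#' @param ds a `curated_dataset`.
#' @param threshold similarity cutoff in `(0, 1]` (default 0.9).
#' @param nbits,radius fingerprint parameters.
#' @return the filtered `curated_dataset` with removals logged.
#' @export
filter_negatives <- function(ds, threshold = 0.9, nbits = 2048L,
                             radius = 2L) {
  stopifnot(inherits(ds, "curated_dataset"))
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  cmp <- ds$compounds
  pos <- cmp[cmp$label == 1L, ]
  neg <- cmp[cmp$label == 0L, ]
  if (nrow(pos) == 0L || nrow(neg) == 0L) return(ds)
  sim <- tanimoto_cross(
    fingerprint(neg, nbits = nbits, radius = radius),
    fingerprint(pos, nbits = nbits, radius = radius)
  )
  maxsim <- apply(sim, 1L, max)
  drop <- maxsim > threshold
  log <- ds$curation_log
  if (any(drop)) {
    log <- rbind(log, log_entry(
      sprintf("similarity_filter>%g", threshold), neg$id[drop],
      sprintf("max Tanimoto to positives %.4f", maxsim[drop])
    ))
  }
  keep <- cmp$label == 1L | !(cmp$id %in% neg$id[drop])
  out <- cmp[keep, ]
  rownames(out) <- NULL
  new_curated_dataset(out, log)
}

subset_dataset <- function(ds, idx) {
  out <- ds$compounds[idx, ]
  rownames(out) <- NULL
  new_curated_dataset(out, ds$curation_log)
}

# stratified index split shared by stratified_split() and the evaluators
split_indices <- function(labels, test_fraction, seed) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("both classes must be present", call. = FALSE)
  test_idx <- integer(0)
  withr::with_seed(seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      n_test <- round(length(idx) * test_fraction)
      if (n_test == 0L || n_test == length(idx)) {
        stop("class ", cl, " would have an empty train or test side; ",
             "adjust test_fraction", call. = FALSE)
      }
      test_idx <- c(test_idx, sample(idx, n_test))
    }
  })
  sort(test_idx)
}

# stratified k-fold assignment used by the cross-validation grid search
stratified_folds <- function(labels, k, seed) {
  stopifnot(k >= 2)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("both classes must be present", call. = FALSE)
  counts <- table(labels)
  if (min(counts) < k) {
    stop("smallest class has ", min(counts), " members; use at most ",
         min(counts), " folds", call. = FALSE)
  }
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# fold assignment with optional grouping: all rows of one group (e.g. the
# replicate embeddings of one compound) land in the same fold
assign_folds <- function(labels, k, seed, groups = NULL) {
  if (is.null(groups)) return(stratified_folds(labels, k, seed))
  stopifnot(length(groups) == length(labels))
  ug <- unique(groups)
  gy <- labels[match(ug, groups)]
  stratified_folds(gy, k, seed)[match(groups, ug)]
}

#' Stratified train/test split
#'
#' Splits a curated dataset into disjoint, exhaustive train and test
#' partitions, preserving the per-class proportions to within one compound.
#' Seeded and reproducible.
#'
#' @param ds a `curated_dataset`.
#' @param test_fraction fraction in `(0, 1)` assigned to the test side.
#' @param seed integer seed.
#' @return `list(train = , test = )`, both `curated_dataset`s.
#' @export
stratified_split <- function(ds, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(ds, "curated_dataset"))
  test_idx <- split_indices(ds$compounds$label, test_fraction, seed)
  list(train = subset_dataset(ds, -test_idx),
       test = subset_dataset(ds, test_idx))
}

#' Oversample positives through stochastic re-embedding
#'
#' Builds the feature matrix of a training partition in which every positive
#' compound is embedded `k` times in separate unseeded batches (so a
#' stochastic embedder yields `k` distinct but intrinsically similar feature
#' rows per active) while negatives are embedded once. This is the
#' embedding-variability analogue of minority oversampling: it balances the
#' classes with real molecules rather than interpolated ones.
#'
#' When `seed` is supplied, each batch uses a distinct child seed derived
#' from it, so runs are reproducible while batches still differ from each
#' other. A deterministic embedder with `k > 1` produces identical replicate
#' rows and triggers a warning.
#'
#' @param train a `curated_dataset` (the partition to augment).
#' @param emb an [embedder()].
#' @param k oversampling factor (>= 1); the augmented positive block has
#'   `k * n_pos` rows.
#' @param mode provenance label recorded on the result: `"leakage_safe"`
#'   (augment after splitting; default) or `"augment_first"` (the whole
#'   dataset was augmented before splitting, which leaks replicate rows of
#'   test actives into training — see [build_training_set()]).
#' @param seed optional master seed.
#' @return an `augmented_set`: `$features` (matrix of
#'   `n_neg + k * n_pos` rows), `$labels`, `$origin` (per-row compound id
#'   and replicate index), `$k`, `$mode`.
#' @export
oversample_positives <- function(train, emb, k = 5L,
                                 mode = c("leakage_safe", "augment_first"),
                                 seed = NULL) {
  stopifnot(inherits(train, "curated_dataset"), inherits(emb, "embedder"))
  mode <- match.arg(mode)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  k <- as.integer(k)
  if (emb$deterministic && k > 1L) {
    warning("deterministic embedder: the ", k,
            " replicates per positive are identical copies", call. = FALSE)
  }
  cmp <- train$compounds
  pos <- cmp[cmp$label == 1L, ]
  neg <- cmp[cmp$label == 0L, ]
  seeds <- if (is.null(seed)) rep(list(NULL), k + 1L) else
    as.list(child_seeds(seed, k + 1L))
  blocks <- vector("list", k)
  origin <- vector("list", k + 1L)
  for (r in seq_len(k)) {
    blocks[[r]] <- embed_molecules(pos, emb, seed = seeds[[r]])
    origin[[r]] <- data.frame(id = pos$id, replicate = r, label = 1L,
                              stringsAsFactors = FALSE)
  }
  neg_feat <- embed_molecules(neg, emb, seed = seeds[[k + 1L]])
  origin[[k + 1L]] <- data.frame(id = neg$id, replicate = 1L, label = 0L,
                                 stringsAsFactors = FALSE)
  features <- do.call(rbind, c(blocks, list(neg_feat)))
  origin <- do.call(rbind, origin)
  structure(list(features = features, labels = origin$label,
                 origin = origin, k = k, mode = mode, embedder = emb$name),
            class = "augmented_set")
}

#' @export
print.augmented_set <- function(x, ...) {
  cat("<augmented_set> ", nrow(x$features), " rows (",
      sum(x$labels == 1L), " positive incl. replicates, k=", x$k, ", mode=",
      x$mode, ")\n", sep = "")
  invisible(x)
}

#' Build an augmented training set plus held-out test features
#'
#' Combines splitting and oversampling in either order. `"leakage_safe"`
#' (default) splits first and augments only the training partition, so no
#' test compound contributes any training row. `"augment_first"` augments
#' the full dataset before splitting rows at random, reproducing the
#' evaluation protocol in which replicate embeddings of a test-set active
#' can appear in training; it inflates test recall and exists for
#' protocol-comparison studies only.
#'
#' @param ds a `curated_dataset`.
#' @param emb an [embedder()].
#' @param k oversampling factor.
#' @param mode `"leakage_safe"` or `"augment_first"`.
#' @param test_fraction held-out fraction.
#' @param seed master seed driving the split and all embedding batches.
#' @return list with `$train` (an `augmented_set`), `$test_features`,
#'   `$test_labels`, `$test_ids`, `$mode`.
#' @export
build_training_set <- function(ds, emb, k = 5L,
                               mode = c("leakage_safe", "augment_first"),
                               test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(ds, "curated_dataset"))
  mode <- match.arg(mode)
  sds <- child_seeds(seed, 3L)
  if (mode == "leakage_safe") {
    parts <- stratified_split(ds, test_fraction, seed = sds[1])
    train <- oversample_positives(parts$train, emb, k = k, mode = mode,
                                  seed = sds[2])
    test_feat <- embed_molecules(parts$test, emb, seed = sds[3])
    list(train = train, test_features = test_feat,
         test_labels = parts$test$compounds$label,
         test_ids = parts$test$compounds$id, mode = mode)
  } else {
    aug <- oversample_positives(ds, emb, k = k, mode = mode, seed = sds[2])
    test_idx <- split_indices(aug$labels, test_fraction, seed = sds[1])
    train <- structure(list(
      features = aug$features[-test_idx, , drop = FALSE],
      labels = aug$labels[-test_idx],
      origin = aug$origin[-test_idx, ], k = aug$k, mode = mode,
      embedder = aug$embedder), class = "augmented_set")
    list(train = train,
         test_features = aug$features[test_idx, , drop = FALSE],
         test_labels = aug$labels[test_idx],
         test_ids = aug$origin$id[test_idx], mode = mode)
  }
}
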