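# High-level predictor bundle: curation output in, screening-ready dual
# model out.

#' Train the dual senolytic predictor
#'
#' End-to-end model construction on a curated dataset: oversample the
#' positives by stochastic re-embedding (factor `k`), train the RBF SVM and
#' the network ensemble on the augmented features, fit the applicability
#' domain on the unaugmented one-row-per-compound embedding of the training
#' set (the same representation the models consume), and record the active
#' fingerprints for novelty annotation.
#'
#' @param ds a `curated_dataset` (typically after [filter_negatives()]).
#' @param emb an [embedder()].
#' @param k oversampling factor (default 5).
#' @param svm_cfg,mlp_cfg model configurations.
#' @param n_sub ensemble size (default 10).
#' @param Z applicability-domain width parameter (default 0.5).
#' @param seed master seed for embedding batches and model training.
#' @return a `seno_predictor` bundle: `$svm`, `$mlp`, `$ad`,
#'   `$active_fps`, `$embedder`, `$meta`.
#' @export
train_predictor <- function(ds, emb, k = 5L, svm_cfg = svm_config(),
                            mlp_cfg = mlp_config(), n_sub = 10L, Z = 0.5,
                            seed = 1L) {
  stopifnot(inherits(ds, "curated_dataset"), inherits(emb, "embedder"))
  sds <- child_seeds(seed, 2L)
  aug <- oversample_positives(ds, emb, k = k, seed = sds[1])
  mlp_cfg$seed <- sds[2] %% .Machine$integer.max
  svm <- train_svm(aug$features, aug$labels, svm_cfg)
  mlp <- train_mlp_ensemble(aug$features, aug$labels, mlp_cfg, n_sub = n_sub)
  base_feat <- embed_molecules(ds$compounds, emb,
                               seed = if (emb$deterministic) NULL else seed)
  ad <- fit_ad(base_feat, Z = Z)
  active_fps <- fingerprint(ds$compounds[ds$compounds$label == 1L, ])
  structure(list(svm = svm, mlp = mlp, ad = ad, active_fps = active_fps,
                 embedder = emb,
                 meta = list(k = k, n_sub = n_sub, Z = Z, seed = seed,
                             n_pos = sum(ds$compounds$label == 1L),
                             n_neg = sum(ds$compounds$label == 0L))),
            class = "seno_predictor")
}

#' @export
print.seno_predictor <- function(x, ...) {
  cat("<seno_predictor> trained on ", x$meta$n_pos, " actives / ",
      x$meta$n_neg, " inactives (k=", x$meta$k, ", ensemble of ",
      x$meta$n_sub, ", embedder=", x$embedder$name, ")\n", sep = "")
  invisible(x)
}

#' Screen a compound library with a trained predictor
#'
#' Canonicalizes the library, embeds it once with a reproducible seed,
#' fingerprints it, and runs [consensus_screen()].
#'
#' @param pred a `seno_predictor`.
#' @param library_table data frame with `id` and `smiles` columns.
#' @param seed embedding seed for the library batch (default derives from
#'   the bundle seed so screening is reproducible).
#' @param normalized_rank see [consensus_screen()].
#' @return prediction records (see [consensus_screen()]).
#' @export
screen_library <- function(pred, library_table, seed = NULL,
                           normalized_rank = FALSE) {
  stopifnot(inherits(pred, "seno_predictor"))
  mol <- molecules(library_table$id, library_table$smiles)
  feats <- embed_molecules(mol, pred$embedder,
                           seed = seed %||% (pred$meta$seed + 1L))
  fps <- fingerprint(mol)
  consensus_screen(mol$id, feats, fps, pred$svm, pred$mlp, pred$ad,
                   pred$active_fps, normalized_rank = normalized_rank)
}

#' Persist / restore a predictor bundle
#'
#' The bundle directory holds the serialized models plus a human-readable
#' `metadata.json` (configurations, seeds, feature provenance).
#'
#' @param pred a `seno_predictor`.
#' @param dir destination directory (created if needed).
#' @rdname bundle_io
#' @export
save_bundle <- function(pred, dir) {
  stopifnot(inherits(pred, "seno_predictor"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(pred, file.path(dir, "predictor.rds"))
  jsonlite::write_json(
    c(pred$meta, list(embedder = pred$embedder$name,
                      embedder_dim = pred$embedder$dim,
                      svm_config = unclass(pred$svm$cfg),
                      mlp_config = unclass(pred$mlp$cfg))),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA,
    null = "null"
  )
  invisible(dir)
}

#' @param dir bundle directory.
#' @rdname bundle_io
#' @export
load_bundle <- function(dir) {
  readRDS(file.path(dir, "predictor.rds"))
}
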