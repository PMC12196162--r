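# Shared fixtures, memoised so the chemistry backend is hit once per suite.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# hand-built fingerprint sets for arithmetic-level tests
toy_fp_set <- function(bits, ids = NULL, nbits = 64L, scheme = "ecfp",
                       radius = 2L) {
  structure(lapply(bits, as.integer), class = "fp_set", scheme = scheme,
            nbits = as.integer(nbits), radius = as.integer(radius),
            ids = ids)
}

# small planted-scaffold library + curated dataset reused across files
small_library <- function() {
  memo("small_library",
       generate_library(n_pos = 30, n_neg = 300, scaffold_overlap = 0.05,
                        label_noise = 0.02, seed = 42))
}

small_dataset <- function() {
  memo("small_dataset", {
    lib <- small_library()
    filter_negatives(assemble_dataset(
      lib[lib$label == 1, c("id", "smiles")],
      lib[lib$label == 0, c("id", "smiles")]
    ))
  })
}

# two gaussian blobs, linearly separable unless sep is small
blob_data <- function(n = 60, d = 5, sep = 4, prevalence = 0.5, seed = 1) {
  withr::with_seed(seed, {
    n1 <- round(n * prevalence)
    n0 <- n - n1
    X <- rbind(matrix(rnorm(n0 * d), n0, d),
               matrix(rnorm(n1 * d, mean = sep / sqrt(d)), n1, d))
    list(X = X, y = c(rep(0, n0), rep(1, n1)))
  })
}

# small training-set compilation shared by model tests
trained_small <- function() {
  memo("trained_small", {
    ds <- small_dataset()
    emb <- mock_embedder(dim = 48, tau = 0.1, base_seed = 7)
    bt <- build_training_set(ds, emb, k = 5, test_fraction = 0.2, seed = 3)
    bt$emb <- emb
    bt$ds <- ds
    bt
  })
}

fast_mlp_cfg <- function(seed = 1L, hidden = 32L) {
  mlp_config(hidden_width = hidden, learning_rate = 0.01,
             max_epochs = 150L, patience = 30L, seed = seed)
}
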