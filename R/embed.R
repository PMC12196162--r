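# Embedder contract: any object of class "embedder" with fields
#   name          - registry key
#   dim           - embedding width
#   deterministic - TRUE if output is a pure function of the molecules
#   fn(smiles, seed) - returns an n x dim numeric matrix
# Chemical language models (e.g. 768-dimensional SMILES transformers) vary
# their output from batch to batch when unseeded; that batch variability is
# what the minority-oversampling strategy exploits, so the contract keeps
# `seed = NULL` meaning "let the embedder vary".

#' Create an embedder object
#'
#' @param name registry key.
#' @param dim embedding width.
#' @param fn function `(smiles, seed)` returning an `n x dim` matrix.
#' @param deterministic does the embedder always return the same matrix for
#'   the same molecules, regardless of seeding?
#' @return an object of class `embedder`.
#' @export
embedder <- function(name, dim, fn, deterministic = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, dim >= 1,
            is.function(fn))
  structure(list(name = name, dim = as.integer(dim), fn = fn,
                 deterministic = isTRUE(deterministic)),
            class = "embedder")
}

#' @export
print.embedder <- function(x, ...) {
  cat("<embedder> ", x$name, " dim=", x$dim,
      if (x$deterministic) " (deterministic)" else " (batch-varying)",
      "\n", sep = "")
  invisible(x)
}

#' Register / fetch embedders by name
#'
#' @param emb an [embedder()] object.
#' @rdname embedder_registry
#' @export
register_embedder <- function(emb) {
  stopifnot(inherits(emb, "embedder"))
  .seno$embedders[[emb$name]] <- emb
  invisible(emb)
}

#' @param name registry key.
#' @rdname embedder_registry
#' @export
get_embedder <- function(name) {
  emb <- .seno$embedders[[name]]
  if (is.null(emb)) stop("unknown embedder: ", name, call. = FALSE)
  emb
}

#' Embed a batch of molecules
#'
#' Runs one embedding batch. With a fixed `seed` the result is bit-identical
#' across calls; with `seed = NULL` a stochastic embedder may return a
#' different matrix per call (this emulates the batch-to-batch variability of
#' pretrained chemical language models and is load-bearing for minority
#' oversampling).
#'
#' @param mol molecule table or character vector of canonical SMILES (may be
#'   empty, giving a `0 x dim` matrix).
#' @param emb an [embedder()] object or a registered embedder name.
#' @param seed optional integer seed for a reproducible batch.
#' @return `n x dim` numeric matrix with a `batch_tag` attribute; row order
#'   matches the input order.
#' @export
embed_molecules <- function(mol, emb, seed = NULL) {
  if (is.character(emb) && length(emb) == 1L) emb <- get_embedder(emb)
  stopifnot(inherits(emb, "embedder"))
  smi <- smiles_of(mol)
  if (length(smi) == 0L) {
    m <- matrix(numeric(0), nrow = 0L, ncol = emb$dim)
  } else {
    m <- emb$fn(smi, seed)
  }
  if (!is.matrix(m) || ncol(m) != emb$dim || nrow(m) != length(smi)) {
    stop("embedder '", emb$name, "' violated its dimension contract",
         call. = FALSE)
  }
  if (length(m) && any(!is.finite(m))) {
    stop("embedder '", emb$name, "' returned non-finite values", call. = FALSE)
  }
  rownames(m) <- ids_of(mol)
  # opaque batch identifier; a counter, not RNG, so embedding never perturbs
  # the caller's random number stream
  .seno$batch_counter <- (.seno$batch_counter %||% 0L) + 1L
  structure(m, batch_tag = sprintf("%s-batch%06d", emb$name,
                                   .seno$batch_counter),
            embedder = emb$name, seed = seed)
}

#' Mock embedder with controllable batch noise
#'
#' A stand-in for a pretrained chemical language model, for testing and
#' synthetic benchmarks. Each molecule's base vector is a pure function of
#' its canonical SMILES: the molecule's ECFP on-bits select rows of a fixed
#' Gaussian random projection (seeded by `base_seed`), which are summed and
#' scaled by `1/sqrt(n_bits_on)`. Structurally similar molecules therefore
#' receive nearby embeddings. Each unseeded batch adds independent
#' `N(0, tau^2)` noise per coordinate, emulating batch-to-batch variability;
#' `tau = 0` makes the embedder fully deterministic.
#'
#' @param dim embedding width (default 768).
#' @param tau batch noise standard deviation (>= 0).
#' @param base_seed seed of the fixed random projection.
#' @param nbits,radius parameters of the underlying ECFP fingerprint.
#' @return an [embedder()] named `"mock"` (dimension and noise recorded in
#'   fields `tau`, `base_seed`).
#' @export
mock_embedder <- function(dim = 768L, tau = 0.1, base_seed = 1L,
                          nbits = 2048L, radius = 2L) {
  stopifnot(dim >= 1, tau >= 0)
  dim <- as.integer(dim)
  proj_env <- new.env(parent = emptyenv())
  fn <- function(smiles, seed = NULL) {
    if (is.null(proj_env$P)) {
      proj_env$P <- withr::with_seed(base_seed,
        matrix(rnorm(nbits * dim), nrow = nbits, ncol = dim))
    }
    fps <- fingerprint(smiles, scheme = "ecfp", nbits = nbits, radius = radius)
    lens <- lengths(unclass(fps))
    B <- Matrix::sparseMatrix(
      i = rep.int(seq_along(fps), lens),
      j = unlist(unclass(fps), use.names = FALSE) + 1L,
      x = 1, dims = c(length(fps), nbits)
    )
    base <- as.matrix(B %*% proj_env$P) / sqrt(pmax(lens, 1L))
    if (tau > 0) {
      noise <- if (is.null(seed)) {
        matrix(rnorm(length(base), sd = tau), nrow = nrow(base))
      } else {
        withr::with_seed(seed,
          matrix(rnorm(length(base), sd = tau), nrow = nrow(base)))
      }
      base <- base + noise
    }
    base
  }
  emb <- embedder("mock", dim, fn, deterministic = tau == 0)
  emb$tau <- tau
  emb$base_seed <- base_seed
  emb
}
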