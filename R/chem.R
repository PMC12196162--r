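#' Canonicalize SMILES strings
#'
#' Maps every input to a single canonical SMILES form so that structurally
#' identical inputs compare equal. Multi-fragment inputs (salts, mixtures)
#' are kept intact by default with a warning; `keep_largest_fragment = TRUE`
#' retains only the fragment with the most heavy atoms.
#'
#' @param smiles character vector of SMILES strings.
#' @param keep_largest_fragment drop all but the largest fragment of
#'   multi-fragment inputs.
#' @return character vector of canonical SMILES, same length as input.
#'   Unparseable input raises a condition of class `senoscreen_parse_error`
#'   carrying the offending strings.
#' @examples
#' \dontrun{
#' canonicalize(c("CCO", "OCC"))  # identical outputs
#' }
#' @export
canonicalize <- function(smiles, keep_largest_fragment = FALSE) {
  stopifnot(is.character(smiles))
  if (any(!nzchar(smiles))) stop("empty SMILES string", call. = FALSE)
  out <- rdkit_cached("canon", smiles)
  raise_parse_errors(out, smiles)
  multi <- grepl(".", out, fixed = TRUE)
  if (any(multi)) {
    if (keep_largest_fragment) {
      frags <- strsplit(out[multi], ".", fixed = TRUE)
      biggest <- vapply(frags, function(f) {
        # heavy-atom proxy: count of alphabetic characters excluding H/h
        f[which.max(nchar(gsub("[^A-GI-Za-gi-z]", "", f)))]
      }, character(1))
      out[multi] <- canonicalize(biggest)
    } else {
      warning(sum(multi), " multi-fragment structure(s) kept intact",
              call. = FALSE)
    }
  }
  out
}

#' Construct a molecule table
#'
#' Builds the canonical molecule representation used across the package: a
#' data frame with unique ids, the input SMILES, and their canonical form.
#'
#' @param id character vector of unique compound identifiers.
#' @param smiles character vector of SMILES, same length as `id`.
#' @param ... passed to [canonicalize()].
#' @return data frame with columns `id`, `input_smiles`, `canonical_smiles`.
#' @export
molecules <- function(id, smiles, ...) {
  stopifnot(length(id) == length(smiles))
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("duplicate molecule ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  data.frame(id = id, input_smiles = smiles,
             canonical_smiles = canonicalize(smiles, ...),
             stringsAsFactors = FALSE)
}

smiles_of <- function(mol) {
  if (inherits(mol, "curated_dataset")) mol <- mol$compounds
  if (is.character(mol)) return(mol)
  if (is.data.frame(mol) && "canonical_smiles" %in% names(mol)) {
    return(mol$canonical_smiles)
  }
  stop("expected SMILES vector or molecule table", call. = FALSE)
}

ids_of <- function(mol) {
  if (inherits(mol, "curated_dataset")) mol <- mol$compounds
  if (is.data.frame(mol) && "id" %in% names(mol)) return(mol$id)
  NULL
}

#' Molecular fingerprints
#'
#' Computes hashed binary fingerprints. `scheme = "ecfp"` is the
#' extended-connectivity (Morgan) fingerprint, default 2048 bits, radius 2;
#' `scheme = "fp2"` is Open Babel's path-based FP2 (1024 bits) and requires
#' the optional ChemmineOB backend.
#'
#' @param mol molecule table from [molecules()] or a character vector of
#'   canonical SMILES.
#' @param scheme `"ecfp"` or `"fp2"`.
#' @param nbits fingerprint length; defaults to 2048 (ecfp) or 1024 (fp2).
#' @param radius atom-environment radius, ecfp only (default 2).
#' @return an object of class `fp_set`: a list of sorted 0-based on-bit
#'   integer vectors with attributes `scheme`, `nbits`, `radius` and `ids`.
#' @export
fingerprint <- function(mol, scheme = c("ecfp", "fp2"), nbits = NULL,
                        radius = NULL) {
  scheme <- match.arg(scheme)
  smi <- smiles_of(mol)
  if (scheme == "ecfp") {
    if (is.null(nbits)) nbits <- 2048L
    if (is.null(radius)) radius <- 2L
    stopifnot(nbits > 0, radius >= 0)
    out <- rdkit_cached("ecfp", smi,
                        c("--nbits", nbits, "--radius", radius))
    raise_parse_errors(out, smi)
    bits <- lapply(strsplit(out, " ", fixed = TRUE), function(x) {
      as.integer(x[nzchar(x)])
    })
  } else {
    if (!is.null(radius)) {
      stop("radius is only meaningful for the ecfp scheme", call. = FALSE)
    }
    if (is.null(nbits)) nbits <- 1024L
    bits <- fp2_bits(smi, nbits)
  }
  structure(bits, class = "fp_set", scheme = scheme, nbits = as.integer(nbits),
            radius = if (scheme == "ecfp") as.integer(radius) else NA_integer_,
            ids = ids_of(mol))
}

# FP2 via the optional Open Babel backend (ChemmineR + ChemmineOB).
fp2_bits <- function(smiles, nbits) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop(structure(
      class = c("senoscreen_capability_error", "error", "condition"),
      list(message = "FP2 requires the ChemmineR/ChemmineOB backend",
           call = NULL)
    ))
  }
  if (nbits != 1024L) stop("FP2 is a fixed 1024-bit scheme", call. = FALSE)
  named <- stats::setNames(smiles, paste0("m", seq_along(smiles)))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(named))
  fps <- ChemmineR::fingerprintOB(sdf, "FP2")
  mat <- ChemmineR::as.matrix(fps)
  lapply(seq_len(nrow(mat)), function(i) which(mat[i, ] != 0) - 1L)
}

#' @export
print.fp_set <- function(x, ...) {
  cat("<fp_set> ", length(x), " molecule(s), scheme=", attr(x, "scheme"),
      " nbits=", attr(x, "nbits"),
      if (!is.na(attr(x, "radius"))) paste0(" radius=", attr(x, "radius")),
      "\n", sep = "")
  invisible(x)
}

#' @export
`[.fp_set` <- function(x, i) {
  structure(unclass(x)[i], class = "fp_set", scheme = attr(x, "scheme"),
            nbits = attr(x, "nbits"), radius = attr(x, "radius"),
            ids = attr(x, "ids")[i])
}

fp_compatible <- function(a, b) {
  if (!identical(attr(a, "scheme"), attr(b, "scheme")) ||
      !identical(attr(a, "nbits"), attr(b, "nbits"))) {
    stop("fingerprint scheme/size mismatch", call. = FALSE)
  }
}

#' Tanimoto similarity of two fingerprints
#'
#' Jaccard index of the on-bit sets, `|A n B| / |A u B|`. The Jaccard
#' distance used for novelty analysis is `1 - tanimoto()`. Two empty
#' fingerprints have undefined similarity; it is reported as 0 with a
#' warning, the conservative choice when low similarity means novelty.
#'
#' @param a,b integer on-bit vectors (elements of an `fp_set`), or two
#'   single-molecule `fp_set`s of matching scheme and size.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (inherits(a, "fp_set") && inherits(b, "fp_set")) {
    fp_compatible(a, b)
    stopifnot(length(a) == 1L, length(b) == 1L)
    a <- a[[1L]]; b <- b[[1L]]
  }
  a <- as.integer(a); b <- as.integer(b)
  u <- length(union(a, b))
  if (u == 0L) {
    warning("both fingerprints empty; similarity defined as 0", call. = FALSE)
    return(0)
  }
  length(intersect(a, b)) / u
}

# Cross Tanimoto similarity matrix between two fp_sets (rows = query,
# columns = reference), computed through a sparse bit-matrix crossproduct.
tanimoto_cross <- function(query, ref) {
  fp_compatible(query, ref)
  nb <- attr(query, "nbits")
  tosparse <- function(fps) {
    lens <- lengths(fps)
    Matrix::sparseMatrix(
      i = rep.int(seq_along(fps), lens),
      j = unlist(fps, use.names = FALSE) + 1L,
      x = 1, dims = c(length(fps), nb)
    )
  }
  A <- tosparse(query); B <- tosparse(ref)
  inter <- as.matrix(A %*% Matrix::t(B))
  un <- outer(lengths(unclass(query)), lengths(unclass(ref)), "+") - inter
  sim <- ifelse(un == 0, 0, inter / un)
  rownames(sim) <- attr(query, "ids")
  colnames(sim) <- attr(ref, "ids")
  sim
}

#' Molecular descriptor vectors
#'
#' Computes the package's fixed 200-descriptor vector (an alphabetically
#' ordered subset of RDKit's 2D descriptors, frozen in
#' `inst/extdata/descriptor_names.txt` for reproducibility). Descriptors
#' that fail on a valid molecule are returned as `NA` and counted in the
#' `n_nonfinite` attribute; invalid molecules raise a parse error.
#'
#' @param mol molecule table or character vector of canonical SMILES.
#' @return numeric matrix, one row per molecule, exactly 200 named columns.
#' @export
descriptors <- function(mol) {
  smi <- smiles_of(mol)
  names_file <- system.file("extdata", "descriptor_names.txt",
                            package = "senoscreen")
  nms <- readLines(names_file)
  out <- rdkit_cached("desc", smi, c("--names", shQuote(names_file)))
  raise_parse_errors(out, smi)
  vals <- lapply(strsplit(out, "\t", fixed = TRUE), as.numeric)
  m <- do.call(rbind, vals)
  colnames(m) <- nms
  rownames(m) <- ids_of(mol)
  nonfinite <- sum(!is.finite(m))
  if (nonfinite > 0) {
    warning(nonfinite, " non-finite descriptor value(s) flagged as NA",
            call. = FALSE)
    m[!is.finite(m)] <- NA_real_
  }
  structure(m, n_nonfinite = nonfinite)
}

#' Descriptor name list
#'
#' The frozen, alphabetically ordered list of the 200 molecular descriptors
#' computed by [descriptors()].
#' @return character vector of length 200.
#' @export
descriptor_names <- function() {
  readLines(system.file("extdata", "descriptor_names.txt",
                        package = "senoscreen"))
}
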