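# Plain-text readers and writers for the table formats the pipeline
# consumes: compound tables (CSV/TSV), feature matrices with a JSON sidecar
# header, and prediction records.

delim_of <- function(path) {
  if (tolower(tools::file_ext(path)) %in% c("tsv", "tab", "txt")) "\t" else ","
}

#' Read a compound table
#'
#' CSV or TSV (by extension) with at least `id` and `smiles` columns;
#' `label` and `provenance` are carried through when present.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_compound_table <- function(path) {
  tab <- read.delim(path, sep = delim_of(path), stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (!all(c("id", "smiles") %in% names(tab))) {
    stop("compound table needs 'id' and 'smiles' columns", call. = FALSE)
  }
  tab$id <- as.character(tab$id)
  tab
}

#' Write a compound table
#'
#' @param tab data frame with `id` and `smiles` columns.
#' @param path destination (CSV or TSV by extension).
#' @export
write_compound_table <- function(tab, path) {
  write.table(tab, path, sep = delim_of(path), row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a compound table from an SDF file
#'
#' Optional reader (requires ChemmineR): molecule titles become ids and
#' structures are exported as SMILES.
#'
#' @param path SDF file path.
#' @return data frame with `id` and `smiles`.
#' @export
read_compound_sdf <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("SDF input requires the ChemmineR/ChemmineOB backend", call. = FALSE)
  }
  sdf <- ChemmineR::read.SDFset(path)
  smi <- ChemmineR::sdf2smiles(sdf)
  data.frame(id = unname(ChemmineR::sdfid(sdf)),
             smiles = as.character(smi), stringsAsFactors = FALSE)
}

#' Write a feature matrix with a JSON sidecar header
#'
#' The matrix goes to a TSV (first column `id`); provenance metadata
#' (feature scheme, dimensions, embedder name and seed, descriptor-list
#' hash, ...) goes to `<path>.json` so downstream stages can verify they
#' are operating in the right feature space.
#'
#' @param x numeric matrix with row names (or `ids` supplied).
#' @param path destination TSV path.
#' @param meta named list of metadata to record.
#' @param ids optional explicit id vector.
#' @export
write_feature_matrix <- function(x, path, meta = list(), ids = NULL) {
  ids <- ids %||% rownames(x) %||% as.character(seq_len(nrow(x)))
  df <- data.frame(id = ids, x, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta$ncol <- ncol(x)
  meta$nrow <- nrow(x)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV path.
#' @return numeric matrix with row names; sidecar metadata in attribute
#'   `"meta"`.
#' @export
read_feature_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
          else NULL
  structure(m, meta = meta)
}

#' Write and read screening prediction records
#'
#' Lossless plain-text round trip of [consensus_screen()] output: numeric
#' columns are printed with 17 significant digits so that
#' `read_predictions(write_predictions(x))` reproduces the records exactly.
#'
#' @param records prediction records data frame.
#' @param path destination TSV path.
#' @rdname predictions_io
#' @export
write_predictions <- function(records, path) {
  out <- records
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname predictions_io
#' @export
read_predictions <- function(path) {
  rec <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  for (col in c("svm_label", "mlp_label", "consensus")) {
    if (col %in% names(rec)) rec[[col]] <- as.integer(rec[[col]])
  }
  if ("in_ad" %in% names(rec)) rec$in_ad <- as.logical(rec$in_ad)
  rec
}
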