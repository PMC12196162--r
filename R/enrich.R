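# Hypergeometric enrichment of predicted hits over source annotations
# (medicinal herbs, targets, or any compound -> category mapping).

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity
#' (delegates to [stats::p.adjust()]); input order is preserved.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order and length.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "BH")
}

#' Hypergeometric source enrichment of predicted hits
#'
#' For every source (herb, target, pathway...), tests whether the hit set
#' contains more of the source's compounds than expected under random draws
#' without replacement: `p = P(X >= k)` with
#' `X ~ Hypergeometric(N, K, n)`, where `N` is the universe size, `K` the
#' source size within the universe, `n` the number of hits and `k` the
#' number of hits in the source. P-values are BH-adjusted across all tested
#' sources. By default the universe is the set of compounds carrying at
#' least one mapping (the convention of standard enrichment tools);
#' `universe = "all"` uses an explicitly supplied id set instead. No source
#' size filter is applied: small sources are legitimate in herb enrichment.
#'
#' @param hits character vector of hit compound ids (must be a subset of
#'   the universe).
#' @param mapping data frame with columns `compound_id`, `source` and
#'   optionally `family`, `genus`.
#' @param universe `"mapped"` (default) or `"all"`.
#' @param universe_ids id set defining the universe when
#'   `universe = "all"`.
#' @param alpha significance level for the `enriched` flag applied to
#'   `p_adj` (default 0.05); all rows are retained regardless.
#' @return data frame sorted by ascending `p_adj`: `source` (plus `family`
#'   and `genus` when mapped), `k`, `K`, `n`, `N`, `p`, `p_adj`,
#'   `enriched`.
#' @export
enrich_sources <- function(hits, mapping, universe = c("mapped", "all"),
                           universe_ids = NULL, alpha = 0.05) {
  universe <- match.arg(universe)
  stopifnot(all(c("compound_id", "source") %in% names(mapping)))
  mapping <- unique(mapping[, intersect(names(mapping),
                                        c("compound_id", "source",
                                          "family", "genus"))])
  uni <- if (universe == "mapped") {
    unique(mapping$compound_id)
  } else {
    if (is.null(universe_ids)) {
      stop('universe = "all" requires universe_ids', call. = FALSE)
    }
    unique(as.character(universe_ids))
  }
  if (length(uni) == 0L) stop("empty universe", call. = FALSE)
  hits <- unique(as.character(hits))
  if (!all(hits %in% uni)) {
    stop("hits must be a subset of the universe", call. = FALSE)
  }
  mapping <- mapping[mapping$compound_id %in% uni, ]
  N <- length(uni)
  n <- length(hits)
  src <- split(mapping$compound_id, mapping$source)
  K <- lengths(lapply(src, unique))
  k <- vapply(src, function(m) length(intersect(unique(m), hits)), numeric(1))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(source = names(src), k = as.integer(k),
                    K = as.integer(K), n = n, N = N, p = p,
                    p_adj = bh_adjust(p), stringsAsFactors = FALSE)
  meta_cols <- intersect(c("family", "genus"), names(mapping))
  if (length(meta_cols)) {
    meta <- mapping[!duplicated(mapping$source),
                    c("source", meta_cols), drop = FALSE]
    out <- merge(out, meta, by = "source", sort = FALSE)
  }
  out$enriched <- out$k > 0 & out$p_adj < alpha
  out <- out[order(out$p_adj, out$p, out$source), ]
  rownames(out) <- NULL
  out
}
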