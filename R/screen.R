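# Applicability-domain gating, dual-model consensus screening, and
# structural-novelty reporting.

#' Fit a distance-to-model applicability domain
#'
#' Computes the mean `D` and standard deviation `sigma` of all pairwise
#' Euclidean distances among the training rows (unordered pairs, self
#' distances excluded; `sigma` uses the population, divide-by-N,
#' convention) and sets the applicability-domain threshold
#' `ADT = D + Z * sigma`. A query compound is inside the domain when the
#' Euclidean distance to its nearest training row is strictly below ADT.
#'
#' @param train_features numeric matrix with at least 2 rows, in the same
#'   feature space used by the deployed models (embeddings by default).
#' @param Z empirical similarity threshold parameter (default 0.5).
#' @return an `ad_model`: `D`, `sigma`, `Z`, `ADT`, `reference` matrix.
#' @export
fit_ad <- function(train_features, Z = 0.5) {
  stopifnot(is.matrix(train_features))
  if (nrow(train_features) < 2L) {
    stop("need at least 2 training rows", call. = FALSE)
  }
  d <- as.numeric(dist(train_features))
  D <- mean(d)
  sigma <- sqrt(mean((d - D)^2))
  structure(list(D = D, sigma = sigma, Z = Z, ADT = D + Z * sigma,
                 reference = train_features),
            class = "ad_model")
}

#' @export
print.ad_model <- function(x, ...) {
  cat(sprintf("<ad_model> D=%.4f sigma=%.4f Z=%.2f ADT=%.4f (%d x %d ref)\n",
              x$D, x$sigma, x$Z, x$ADT, nrow(x$reference),
              ncol(x$reference)))
  invisible(x)
}

# squared Euclidean distances query x reference
cross_dist2 <- function(Q, R) {
  d2 <- outer(rowSums(Q^2), rowSums(R^2), "+") - 2 * Q %*% t(R)
  pmax(d2, 0)
}

#' Nearest-neighbour distance to the applicability-domain reference
#'
#' @param query numeric matrix (or single row vector) in the reference
#'   feature space.
#' @param ad an `ad_model`.
#' @return numeric vector of nearest-neighbour Euclidean distances.
#' @export
ad_distance <- function(query, ad) {
  stopifnot(inherits(ad, "ad_model"))
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  if (ncol(query) != ncol(ad$reference)) {
    stop("query dimension does not match the reference matrix", call. = FALSE)
  }
  sqrt(apply(cross_dist2(query, ad$reference), 1L, min))
}

#' Applicability-domain membership
#'
#' `TRUE` iff the nearest-neighbour distance is strictly less than the ADT;
#' a query at exactly the threshold is outside. Membership is monotone in
#' `Z`: increasing `Z` never moves a query from inside to outside.
#'
#' @inheritParams ad_distance
#' @return logical vector.
#' @export
in_ad <- function(query, ad) {
  ad_distance(query, ad) < ad$ADT
}

#' Structural novelty against the active training set
#'
#' For each query fingerprint, the maximum Tanimoto similarity to the
#' active training compounds (`match_degree`) and the identity of the
#' nearest active (`match_id`; ties broken by lexicographically smallest
#' id). Low `match_degree` marks a structurally novel prediction.
#'
#' @param query an `fp_set` of query fingerprints.
#' @param actives a non-empty `fp_set` of training actives with ids.
#' @return data frame with columns `match_degree`, `match_id`.
#' @export
novelty <- function(query, actives) {
  stopifnot(inherits(query, "fp_set"), inherits(actives, "fp_set"))
  if (length(actives) == 0L) stop("empty active set", call. = FALSE)
  ids <- attr(actives, "ids") %||% as.character(seq_along(actives))
  sim <- tanimoto_cross(query, actives)
  best <- apply(sim, 1L, function(row) {
    m <- max(row)
    list(degree = m, id = min(ids[row == m]))
  })
  data.frame(
    match_degree = vapply(best, `[[`, numeric(1), "degree"),
    match_id = vapply(best, `[[`, character(1), "id"),
    stringsAsFactors = FALSE
  )
}

#' Dual-model consensus screening of a compound library
#'
#' Scores every library compound with both models, applies the fixed
#' decision thresholds (SVM score strictly greater than 0, MLP probability
#' strictly greater than 0.5), keeps the conjunction as the consensus call,
#' annotates applicability-domain membership and structural novelty, and
#' ranks by `rank_score = svm_score + mlp_prob` (the raw-sum convention;
#' `normalized_rank = TRUE` min-max rescales the SVM score to `[0, 1]`
#' before summing). Out-of-domain compounds are flagged, never dropped.
#'
#' @param ids character vector of library compound ids.
#' @param features library feature matrix (same scheme/space as training).
#' @param query_fps `fp_set` of library fingerprints (for novelty).
#' @param svm a `seno_svm` model.
#' @param mlp a `seno_mlp` or `seno_mlp_ensemble` model.
#' @param ad an `ad_model`.
#' @param active_fps `fp_set` of training actives.
#' @param normalized_rank use the normalized ranking variant.
#' @return a data frame of prediction records, one row per compound,
#'   consensus positives first in descending `rank_score` (ties by id):
#'   `id`, `svm_score`, `svm_label`, `mlp_prob`, `mlp_label`, `consensus`,
#'   `rank_score`, `in_ad`, `match_degree`, `match_id`.
#' @export
consensus_screen <- function(ids, features, query_fps, svm, mlp, ad,
                             active_fps, normalized_rank = FALSE) {
  stopifnot(length(ids) == nrow(features), length(query_fps) == length(ids))
  if (ncol(features) != svm$dim || ncol(features) != ncol(ad$reference)) {
    stop("feature space does not match the model bundle", call. = FALSE)
  }
  svm_score <- predict(svm, features)
  mlp_prob <- predict(mlp, features)
  svm_label <- as.integer(svm_score > 0)
  mlp_label <- as.integer(mlp_prob > 0.5)
  nov <- novelty(query_fps, active_fps)
  rank_base <- if (normalized_rank && length(svm_score) > 1L &&
                   diff(range(svm_score)) > 0) {
    (svm_score - min(svm_score)) / diff(range(svm_score))
  } else {
    svm_score
  }
  rec <- data.frame(
    id = as.character(ids),
    svm_score = svm_score, svm_label = svm_label,
    mlp_prob = mlp_prob, mlp_label = mlp_label,
    consensus = svm_label * mlp_label,
    rank_score = rank_base + mlp_prob,
    in_ad = in_ad(features, ad),
    match_degree = nov$match_degree, match_id = nov$match_id,
    stringsAsFactors = FALSE
  )
  rec <- rec[order(-rec$consensus, -rec$rank_score, rec$id), ]
  rownames(rec) <- NULL
  rec
}

#' Count structurally novel consensus hits
#'
#' Counts consensus-positive records whose `match_degree` is strictly below
#' each threshold (the default thresholds 0.3 and 0.5 mirror common novelty
#' reporting cutoffs), plus a 0.1-wide histogram of the match-degree
#' distribution for plotting. Unsorted or duplicated thresholds are
#' normalized with a warning.
#'
#' @param records prediction records from [consensus_screen()].
#' @param thresholds numeric cutoffs (default `c(0.3, 0.5)`).
#' @return data frame `threshold`, `count`; the binned distribution is
#'   attached as attribute `"histogram"`.
#' @export
novelty_histogram <- function(records, thresholds = c(0.3, 0.5)) {
  stopifnot("match_degree" %in% names(records))
  norm <- sort(unique(thresholds))
  if (!identical(norm, as.numeric(thresholds))) {
    warning("thresholds normalized to sorted unique values", call. = FALSE)
  }
  hits <- records[records$consensus == 1L, ]
  counts <- vapply(norm, function(t) sum(hits$match_degree < t), numeric(1))
  breaks <- seq(0, 1, by = 0.1)
  h <- table(cut(hits$match_degree, breaks, include.lowest = TRUE,
                 right = FALSE))
  structure(data.frame(threshold = norm, count = counts),
            histogram = as.data.frame(h, responseName = "count"))
}
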