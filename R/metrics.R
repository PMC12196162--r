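# Classification metrics, precision-recall analysis, and the repeated
# random-split evaluation protocol.

#' Confusion-matrix metrics at a decision threshold
#'
#' Computes accuracy, precision, recall, F1, Matthews correlation
#' coefficient and rank-based AUC from labels and real-valued scores, with
#' the prediction rule `score > threshold`. Metrics with a zero denominator
#' are reported as 0 and named in `$degenerate` (rather than propagating
#' NaN) so that averaged cross-validation reports stay computable; AUC on a
#' single-class truth vector is `NA` with a flag.
#'
#' @param y_true binary labels (0/1).
#' @param scores real-valued scores, same length.
#' @param threshold decision threshold (strict `>`); 0 for SVM scores,
#'   0.5 for probabilities.
#' @return a `metrics_report` list: `tp`, `tn`, `fp`, `fn`, `accuracy`,
#'   `precision`, `recall`, `f1`, `mcc`, `auc`, `degenerate`.
#' @export
compute_metrics <- function(y_true, scores, threshold = 0.5) {
  if (length(y_true) != length(scores)) stop("length mismatch", call. = FALSE)
  stopifnot(is_binary01(y_true))
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & y_true == 1)
  tn <- sum(pred == 0L & y_true == 0)
  fp <- sum(pred == 1L & y_true == 0)
  fn <- sum(pred == 0L & y_true == 1)
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      return(0)
    }
    num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  f1 <- safe(2 * precision * recall, precision + recall, "f1")
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) {
    degenerate <- c(degenerate, "mcc")
    0
  } else {
    (tp * tn - fp * fn) / mcc_den
  }
  auc <- if (length(unique(y_true)) < 2L) {
    degenerate <- c(degenerate, "auc")
    NA_real_
  } else {
    auc_score(y_true, scores)
  }
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = (tp + tn) / length(y_true),
                 precision = precision, recall = recall, f1 = f1,
                 mcc = mcc, auc = auc, degenerate = degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics> acc=%.3f prec=%.3f rec=%.3f F1=%.3f MCC=%.3f AUC=%s\n",
    x$accuracy, x$precision, x$recall, x$f1, x$mcc,
    ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  if (length(x$degenerate)) {
    cat("  degenerate:", paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC, invariant under strictly monotone
#' transforms of the scores; ties receive mid-ranks.
#'
#' @param y_true binary labels with both classes present.
#' @param scores real-valued scores.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(y_true, scores) {
  stopifnot(is_binary01(y_true), length(unique(y_true)) == 2L)
  r <- rank(scores)
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall curve and area
#'
#' Computes the precision-recall curve over the distinct score thresholds
#' (descending) and its area as the step-wise sum
#' `sum((R_i - R_{i-1}) * P_i)` (the average-precision convention, which
#' avoids the optimism of trapezoidal PR interpolation).
#'
#' @param y_true binary labels with both classes present.
#' @param scores real-valued scores.
#' @return list `$curve` (data frame: threshold, recall, precision) and
#'   `$auprc`.
#' @export
pr_curve <- function(y_true, scores) {
  stopifnot(is_binary01(y_true), length(unique(y_true)) == 2L)
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]; s <- scores[ord]
  cum_tp <- cumsum(y)
  cum_fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)  # last index of each distinct score
  tp <- cum_tp[last]; fp <- cum_fp[last]
  n_pos <- sum(y_true)
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  auprc <- sum(diff(c(0, recall)) * precision)
  list(curve = data.frame(threshold = s[last], recall = recall,
                          precision = precision),
       auprc = auprc)
}

#' Bootstrapped precision-recall analysis
#'
#' Point estimate of the auPRC on the full data (identical to
#' [pr_curve()]), plus a percentile confidence interval and curve band from
#' bootstrap resamples with replacement. Resamples that lose one class
#' entirely are redrawn. The curve band interpolates precision on a fixed
#' recall grid, taking at each recall the precision of the smallest
#' threshold reaching it.
#'
#' @param y_true binary labels with both classes present.
#' @param scores real-valued scores.
#' @param n_boot number of bootstrap resamples (>= 2, default 100).
#' @param ci confidence level (default 0.95).
#' @param seed integer seed.
#' @return list `$auprc`, `$ci = c(lo, hi)`, `$curve` (recall grid with
#'   precision point estimate and band), `$boot_auprc`.
#' @export
pr_curve_bootstrap <- function(y_true, scores, n_boot = 100L, ci = 0.95,
                               seed = 1L) {
  if (n_boot < 2) stop("n_boot must be >= 2", call. = FALSE)
  point <- pr_curve(y_true, scores)
  grid <- seq(0, 1, by = 0.01)
  interp <- function(curve) {
    # precision at the earliest threshold whose recall reaches r
    idx <- findInterval(grid, curve$recall, left.open = TRUE) + 1L
    p <- rep(NA_real_, length(grid))
    ok <- idx <= nrow(curve)
    p[ok] <- curve$precision[idx[ok]]
    p[!ok] <- curve$precision[nrow(curve)]
    p[grid == 0] <- curve$precision[1]
    p
  }
  n <- length(y_true)
  boot_auprc <- numeric(n_boot)
  boot_prec <- matrix(NA_real_, n_boot, length(grid))
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        if (length(unique(y_true[idx])) == 2L) break
      }
      pc <- pr_curve(y_true[idx], scores[idx])
      boot_auprc[b] <- pc$auprc
      boot_prec[b, ] <- interp(pc$curve)
    }
  })
  alpha <- (1 - ci) / 2
  band <- apply(boot_prec, 2L, quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE)
  list(auprc = point$auprc,
       ci = unname(quantile(boot_auprc, c(alpha, 1 - alpha))),
       curve = data.frame(recall = grid, precision = interp(point$curve),
                          lo = band[1, ], hi = band[2, ]),
       boot_auprc = boot_auprc)
}

#' Repeated random-split evaluation
#'
#' Runs `n_iter` stratified random splits, refits the supplied pipeline on
#' each training side, scores the test side, and averages the metric
#' reports. The reported value of every metric is the arithmetic mean over
#' iterations; per-iteration reports are retained. The seed stream is
#' reproducible from the master seed.
#'
#' @param ds the dataset object handed to `pipeline` (a `curated_dataset`,
#'   or any list with a `labels` element when `labels` is not given).
#' @param pipeline function `(ds, train_idx, test_idx, seed)` returning
#'   real-valued scores for the test rows.
#' @param labels binary label vector (defaults to the dataset's labels).
#' @param n_iter number of repeats (default 20).
#' @param test_fraction held-out fraction per split (default 0.2).
#' @param seed master seed.
#' @param threshold decision threshold passed to [compute_metrics()].
#' @return list `$mean` (named numeric vector of averaged metrics),
#'   `$per_iteration` (data frame, one row per split).
#' @export
repeated_random_split_eval <- function(ds, pipeline, labels = NULL,
                                       n_iter = 20L, test_fraction = 0.2,
                                       seed = 1L, threshold = 0.5) {
  if (is.null(labels)) {
    labels <- if (inherits(ds, "curated_dataset")) ds$compounds$label
              else ds$labels
  }
  stopifnot(!is.null(labels), n_iter >= 1)
  seeds <- child_seeds(seed, 2L * n_iter)
  keep <- c("accuracy", "precision", "recall", "f1", "mcc", "auc")
  rows <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    res <- tryCatch({
      test_idx <- split_indices(labels, test_fraction, seeds[i])
      sc <- pipeline(ds, setdiff(seq_along(labels), test_idx), test_idx,
                     seeds[n_iter + i])
      compute_metrics(labels[test_idx], sc, threshold = threshold)
    }, error = function(e) {
      stop("iteration ", i, " failed: ", conditionMessage(e), call. = FALSE)
    })
    rows[[i]] <- as.data.frame(res[keep])
  }
  per_iter <- do.call(rbind, rows)
  per_iter$iteration <- seq_len(n_iter)
  list(mean = colMeans(per_iter[keep], na.rm = TRUE),
       per_iteration = per_iter)
}

#' Lifespan extension rate
#'
#' Reporting utility for whole-organism assays: the percent change of the
#' treated mean lifespan over the control mean,
#' `100 * (treated - control) / control`, rounded half away from zero to
#' one decimal.
#'
#' @param treated_mean_days mean lifespan under treatment (days).
#' @param control_mean_days mean lifespan of the matched control (> 0).
#' @return percent extension, one decimal.
#' @export
lifespan_extension_rate <- function(treated_mean_days, control_mean_days) {
  if (any(control_mean_days <= 0)) {
    stop("control mean lifespan must be positive", call. = FALSE)
  }
  round_half_away(100 * (treated_mean_days - control_mean_days) /
                    control_mean_days, 1L)
}
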