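# The dual predictor: a maximum-margin classifier (RBF SVM with balanced
# class weights, exposing a signed decision score thresholded at 0) and an
# ensemble of single-hidden-layer neural networks (probability thresholded
# at 0.5).

#' SVM configuration
#'
#' Defaults follow the tuned senolytic predictor: RBF kernel, `C = 20`,
#' balanced class weights (weight of class c is `n / (2 * n_c)`).
#'
#' @param C cost parameter (> 0).
#' @param kernel kernel name (`"radial"`).
#' @param class_weight `"balanced"` or `NULL` for unweighted.
#' @param gamma optional RBF width; default `1 / ncol(X)`.
#' @return a `svm_config` list.
#' @export
svm_config <- function(C = 20, kernel = "radial", class_weight = "balanced",
                       gamma = NULL) {
  stopifnot(C > 0)
  structure(list(C = C, kernel = kernel, class_weight = class_weight,
                 gamma = gamma), class = "svm_config")
}

#' Train the margin classifier
#'
#' Fits an RBF support vector machine returning a real-valued decision
#' score per compound, oriented so that positive scores mean the positive
#' class; the predicted label is `score > 0`.
#'
#' @param X numeric feature matrix.
#' @param y binary labels (0/1), both classes present.
#' @param cfg a [svm_config()].
#' @return a `seno_svm` model; `predict()` returns the signed score.
#' @export
train_svm <- function(X, y, cfg = svm_config()) {
  stopifnot(is.matrix(X), nrow(X) == length(y), is_binary01(y))
  if (length(unique(y)) < 2L) stop("single-class input", call. = FALSE)
  yf <- factor(y, levels = c("0", "1"))
  wts <- NULL
  if (identical(cfg$class_weight, "balanced")) {
    tab <- table(yf)
    wts <- as.numeric(length(y) / (2 * tab))
    names(wts) <- names(tab)
  }
  fit <- e1071::svm(X, yf, kernel = cfg$kernel, cost = cfg$C,
                    gamma = cfg$gamma %||% (1 / ncol(X)),
                    class.weights = wts, scale = FALSE)
  dv <- attr(predict(fit, X, decision.values = TRUE), "decision.values")[, 1]
  flip <- mean(dv[y == 1]) < mean(dv[y == 0])
  structure(list(fit = fit, flip = flip, cfg = cfg, dim = ncol(X)),
            class = "seno_svm")
}

#' @param object a `seno_svm` model.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return numeric vector of signed decision scores.
#' @rdname train_svm
#' @export
predict.seno_svm <- function(object, newdata, ...) {
  stopifnot(ncol(newdata) == object$dim)
  dv <- attr(predict(object$fit, newdata, decision.values = TRUE),
             "decision.values")[, 1]
  unname(if (object$flip) -dv else dv)
}

#' MLP configuration
#'
#' A single hidden layer of rectified units trained full-batch with Adam,
#' cross-entropy loss, inverted dropout on the hidden layer, and early
#' stopping when the (dropout-free) training loss has not improved for
#' `patience` consecutive epochs. The hidden width is not fixed by the
#' reference protocol; 256 is the package default and is tunable through
#' [grid_search()].
#'
#' @param hidden_width hidden units (default 256).
#' @param learning_rate Adam step size (default 1e-4).
#' @param dropout drop probability in `[0, 1)` (default 0.5).
#' @param max_epochs training epoch cap (default 3000).
#' @param patience early-stopping patience in epochs (< `max_epochs`).
#' @param seed integer seed for initialization and dropout masks.
#' @return an `mlp_config` list.
#' @export
mlp_config <- function(hidden_width = 256L, learning_rate = 1e-4,
                       dropout = 0.5, max_epochs = 3000L, patience = 100L,
                       seed = 1L) {
  stopifnot(hidden_width >= 1, learning_rate > 0,
            dropout >= 0, dropout < 1, patience < max_epochs)
  structure(list(hidden_width = as.integer(hidden_width),
                 learning_rate = learning_rate, dropout = dropout,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "mlp_config")
}

#' Train the single-hidden-layer network
#'
#' @param X numeric feature matrix (finite values).
#' @param y binary labels (0/1), both classes present.
#' @param cfg an [mlp_config()].
#' @return a `seno_mlp` model; `predict()` returns probabilities in
#'   `[0, 1]`. Seeded runs are bit-reproducible. Training aborts with an
#'   error if the loss diverges to a non-finite value.
#' @export
train_mlp <- function(X, y, cfg = mlp_config()) {
  stopifnot(is.matrix(X), nrow(X) == length(y), is_binary01(y))
  if (length(unique(y)) < 2L) stop("single-class input", call. = FALSE)
  if (any(!is.finite(X))) stop("non-finite features", call. = FALSE)
  n <- nrow(X); d <- ncol(X); h <- cfg$hidden_width
  withr::with_seed(cfg$seed, {
    W1 <- matrix(rnorm(d * h, sd = sqrt(2 / d)), d, h)
    b1 <- numeric(h)
    W2 <- matrix(rnorm(h, sd = sqrt(2 / h)), h, 1)
    b2 <- 0
    adam <- lapply(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2), function(p) {
      list(m = p * 0, v = p * 0)
    })
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0L
    best <- list(loss = Inf, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    stall <- 0L
    epochs_run <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      A1 <- sweep(X %*% W1, 2L, b1, "+")
      H <- pmax(A1, 0)
      if (cfg$dropout > 0) {
        M <- matrix((runif(n * h) >= cfg$dropout) / (1 - cfg$dropout), n, h)
        Hd <- H * M
      } else {
        M <- NULL
        Hd <- H
      }
      pr <- plogis(drop(Hd %*% W2) + b2)
      dz <- matrix((pr - y) / n, ncol = 1)
      gW2 <- crossprod(Hd, dz)
      gb2 <- sum(dz)
      dH <- (dz %*% t(W2)) * (A1 > 0)
      if (!is.null(M)) dH <- dH * M
      gW1 <- crossprod(X, dH)
      gb1 <- colSums(dH)
      t_step <- t_step + 1L
      upd <- function(p, g, slot) {
        s <- adam[[slot]]
        s$m <- beta1 * s$m + (1 - beta1) * g
        s$v <- beta2 * s$v + (1 - beta2) * g^2
        adam[[slot]] <<- s
        mhat <- s$m / (1 - beta1^t_step)
        vhat <- s$v / (1 - beta2^t_step)
        p - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
      }
      W1 <- upd(W1, gW1, "W1"); b1 <- upd(b1, gb1, "b1")
      W2 <- upd(W2, gW2, "W2"); b2 <- upd(b2, gb2, "b2")

      # early stopping monitors the dropout-free training loss
      p_clean <- plogis(drop(pmax(sweep(X %*% W1, 2L, b1, "+"), 0) %*% W2)
                        + b2)
      p_clip <- pmin(pmax(p_clean, 1e-12), 1 - 1e-12)
      loss <- -mean(y * log(p_clip) + (1 - y) * log(1 - p_clip))
      if (!is.finite(loss)) stop("training loss diverged", call. = FALSE)
      epochs_run <- epoch
      if (loss < best$loss - 1e-10) {
        best <- list(loss = loss, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
  })
  structure(list(W1 = best$W1, b1 = best$b1, W2 = best$W2, b2 = best$b2,
                 cfg = cfg, dim = d, epochs_run = epochs_run,
                 train_loss = best$loss),
            class = "seno_mlp")
}

#' @param object a `seno_mlp` model.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return probabilities in `[0, 1]`.
#' @rdname train_mlp
#' @export
predict.seno_mlp <- function(object, newdata, ...) {
  stopifnot(ncol(newdata) == object$dim)
  H <- pmax(sweep(newdata %*% object$W1, 2L, object$b1, "+"), 0)
  unname(plogis(drop(H %*% object$W2) + object$b2))
}

#' Train an ensemble of networks differing only by seed
#'
#' The ensemble probability is the arithmetic mean of the sub-model
#' probabilities; sub-model `i` uses seed `cfg$seed + i - 1`.
#'
#' @param X,y as in [train_mlp()].
#' @param cfg an [mlp_config()].
#' @param n_sub number of sub-models (default 10).
#' @return a `seno_mlp_ensemble`; `predict()` returns the mean probability.
#' @export
train_mlp_ensemble <- function(X, y, cfg = mlp_config(), n_sub = 10L) {
  if (n_sub < 1) stop("n_sub must be >= 1", call. = FALSE)
  subs <- lapply(seq_len(n_sub), function(i) {
    sub_cfg <- cfg
    sub_cfg$seed <- cfg$seed + i - 1L
    train_mlp(X, y, sub_cfg)
  })
  structure(list(models = subs, cfg = cfg, n_sub = as.integer(n_sub),
                 dim = ncol(X)),
            class = "seno_mlp_ensemble")
}

#' @param object a `seno_mlp_ensemble`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @rdname train_mlp_ensemble
#' @export
predict.seno_mlp_ensemble <- function(object, newdata, ...) {
  probs <- vapply(object$models, function(m) predict(m, newdata),
                  numeric(nrow(newdata)))
  if (nrow(newdata) == 1L) probs <- matrix(probs, nrow = 1L)
  rowMeans(probs)
}

#' Cross-validated grid search
#'
#' Exhaustively evaluates a configuration grid by stratified k-fold
#' cross-validation. The default winner maximises mean F1 (computed at the
#' model family's decision threshold: 0 for the SVM score, 0.5 for the MLP
#' probability) with mean AUC as tiebreak; `selection = "auc"` swaps the
#' two. The full results table is retained.
#'
#' When the rows of `X` are replicate embeddings of the same compounds
#' (an oversampled training set), pass the per-row compound ids as
#' `groups`: folds are then assigned per compound so that no compound's
#' replicates straddle a fold boundary, which would otherwise let
#' high-capacity configurations win by memorising replicates.
#'
#' @param family `"svm"` or `"mlp"`.
#' @param grid data frame whose columns are config fields (e.g. `C`,
#'   `gamma` for svm; `hidden_width`, `learning_rate` for mlp).
#' @param X,y training data.
#' @param folds number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param selection model-selection metric, `"f1"` (default) or `"auc"`.
#' @param groups optional per-row grouping vector (e.g. compound ids).
#' @return list with `$best` (config as a one-row data frame), `$results`
#'   (grid with mean_f1 and mean_auc columns).
#' @export
grid_search <- function(family = c("svm", "mlp"), grid, X, y, folds = 5L,
                        seed = 1L, selection = c("f1", "auc"),
                        groups = NULL) {
  family <- match.arg(family)
  selection <- match.arg(selection)
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  fold <- assign_folds(y, folds, seed, groups = groups)
  threshold <- if (family == "svm") 0 else 0.5
  eval_cfg <- function(row) {
    f1s <- aucs <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- !tr
      model <- if (family == "svm") {
        cfg <- do.call(svm_config, row[intersect(names(row),
          c("C", "kernel", "class_weight", "gamma"))])
        train_svm(X[tr, , drop = FALSE], y[tr], cfg)
      } else {
        cfg <- do.call(mlp_config, row[intersect(names(row),
          c("hidden_width", "learning_rate", "dropout", "max_epochs",
            "patience", "seed"))])
        train_mlp(X[tr, , drop = FALSE], y[tr], cfg)
      }
      sc <- predict(model, X[te, , drop = FALSE])
      m <- compute_metrics(y[te], sc, threshold = threshold)
      f1s[f] <- m$f1
      aucs[f] <- if (is.na(m$auc)) 0 else m$auc
    }
    c(mean_f1 = mean(f1s), mean_auc = mean(aucs))
  }
  scores <- t(vapply(seq_len(nrow(grid)), function(i) {
    eval_cfg(as.list(grid[i, , drop = FALSE]))
  }, numeric(2)))
  results <- cbind(grid, scores)
  best_i <- if (selection == "f1") {
    order(-results$mean_f1, -results$mean_auc)[1]
  } else {
    order(-results$mean_auc, -results$mean_f1)[1]
  }
  list(best = grid[best_i, , drop = FALSE], results = results)
}
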