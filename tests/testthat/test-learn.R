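test_that("the margin classifier separates separable blobs", {
  b <- blob_data(n = 80, d = 4, sep = 6, seed = 2)
  fit <- train_svm(b$X, b$y)
  sc <- predict(fit, b$X)
  expect_identical(as.integer(sc > 0), as.integer(b$y))
  expect_error(train_svm(b$X, rep(1, 80)), "single-class")
})

test_that("balanced class weights do not hurt minority recall", {
  b <- blob_data(n = 200, d = 4, sep = 2, prevalence = 0.1, seed = 5)
  sp <- senoscreen:::split_indices(b$y, 0.3, seed = 1)
  Xtr <- b$X[-sp, ]; ytr <- b$y[-sp]; Xte <- b$X[sp, ]; yte <- b$y[sp]
  bal <- compute_metrics(yte, predict(train_svm(Xtr, ytr), Xte), 0)
  unw <- compute_metrics(
    yte, predict(train_svm(Xtr, ytr, svm_config(class_weight = NULL)), Xte),
    0)
  expect_gte(bal$recall, unw$recall)
})

test_that("network probabilities are valid, seeded, and discriminative", {
  b <- blob_data(n = 100, d = 6, sep = 5, seed = 3)
  sp <- senoscreen:::split_indices(b$y, 0.3, seed = 2)
  Xtr <- b$X[-sp, ]; ytr <- b$y[-sp]
  for (s in 1:5) {
    fit <- train_mlp(Xtr, ytr, fast_mlp_cfg(seed = s))
    p <- predict(fit, b$X[sp, ])
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(auc_score(b$y[sp], p), 0.95)
  }
  f1 <- train_mlp(Xtr, ytr, fast_mlp_cfg(seed = 42))
  f2 <- train_mlp(Xtr, ytr, fast_mlp_cfg(seed = 42))
  expect_identical(f1$W1, f2$W1)
  expect_identical(predict(f1, b$X), predict(f2, b$X))
  expect_error(train_mlp(cbind(Xtr, NA), ytr, fast_mlp_cfg()), "finite")
})

test_that("early stopping halts before the epoch cap on easy data", {
  b <- blob_data(n = 60, d = 3, sep = 8, seed = 9)
  cfg <- mlp_config(hidden_width = 8, learning_rate = 0.05,
                    max_epochs = 2000, patience = 20, seed = 1)
  fit <- train_mlp(b$X, b$y, cfg)
  expect_lt(fit$epochs_run, 2000)
})

test_that("the ensemble is the arithmetic mean of its sub-models", {
  b <- blob_data(n = 80, d = 4, sep = 4, seed = 7)
  cfg <- fast_mlp_cfg(seed = 5, hidden = 16)
  ens <- train_mlp_ensemble(b$X, b$y, cfg, n_sub = 3)
  probs <- sapply(ens$models, function(m) predict(m, b$X))
  expect_equal(predict(ens, b$X), rowMeans(probs))
  one <- train_mlp_ensemble(b$X, b$y, cfg, n_sub = 1)
  expect_equal(predict(one, b$X), predict(train_mlp(b$X, b$y, cfg), b$X))
  expect_error(train_mlp_ensemble(b$X, b$y, cfg, n_sub = 0), "n_sub")
})

test_that("averaging reduces across-seed prediction variance", {
  b <- blob_data(n = 60, d = 4, sep = 2, seed = 13)
  cfg0 <- fast_mlp_cfg(hidden = 8)
  test_point <- matrix(rep(0.5, 4), 1)
  sub_p <- ens_p <- numeric(6)
  for (s in 1:6) {
    cfg <- cfg0; cfg$seed <- 100 * s
    ens <- train_mlp_ensemble(b$X, b$y, cfg, n_sub = 4)
    ens_p[s] <- predict(ens, test_point)
    sub_p[s] <- predict(ens$models[[1]], test_point)
  }
  expect_lte(var(ens_p), var(sub_p))
})

test_that("grid search picks the directly-verified best configuration", {
  # ring-within-ring data: the RBF kernel must be narrow enough to bend,
  # so a vanishing gamma underfits while gamma = 1 separates
  withr::with_seed(21, {
    n <- 120
    r <- c(runif(n / 2, 0, 0.5), runif(n / 2, 1.2, 1.6))
    th <- runif(n, 0, 2 * pi)
    X <- cbind(r * cos(th), r * sin(th))
    y <- rep(c(1, 0), each = n / 2)
  })
  grid <- data.frame(C = 20, gamma = c(1e-5, 1))
  gs <- grid_search("svm", grid, X, y, folds = 5, seed = 3)
  # independent verification: evaluate both grid points directly
  fold <- senoscreen:::stratified_folds(y, 5, 3)
  direct <- sapply(grid$gamma, function(g) {
    mean(sapply(1:5, function(f) {
      fit <- train_svm(X[fold != f, ], y[fold != f],
                       svm_config(C = 20, gamma = g))
      compute_metrics(y[fold == f], predict(fit, X[fold == f, ]), 0)$f1
    }))
  })
  expect_identical(gs$best$gamma, grid$gamma[which.max(direct)])
  expect_identical(gs$best$gamma, 1)
  gs2 <- grid_search("svm", grid, X, y, folds = 5, seed = 3)
  expect_identical(gs$best, gs2$best)
  one <- grid_search("svm", data.frame(C = 7), X, y, folds = 5, seed = 3)
  expect_identical(one$best$C, 7)
})

test_that("confusion-matrix metrics match the stated formulas", {
  # TP=3, FP=1, FN=1, TN=5
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  s <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.1, 0.1, 0.1, 0.2, 0.3)
  m <- compute_metrics(y, s, threshold = 0.5)
  expect_identical(c(m$tp, m$fp, m$fn, m$tn), c(3L, 1L, 1L, 5L))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(m$mcc, 14 / 24)
  perfect <- compute_metrics(y, y, threshold = 0.5)
  expect_true(all(unlist(perfect[c("accuracy", "precision", "recall",
                                   "f1", "mcc", "auc")]) == 1))
  inverted <- compute_metrics(y, 1 - y, threshold = 0.5)
  expect_identical(inverted$mcc, -1)
  none <- compute_metrics(c(1, 0, 1), c(0.1, 0.2, 0.3), threshold = 0.9)
  expect_identical(none$precision, 0)
  expect_true("precision" %in% none$degenerate)
  expect_identical(none$recall, 0)
  single <- compute_metrics(c(1, 1), c(0.2, 0.9))
  expect_true(is.na(single$auc))
  expect_error(compute_metrics(c(1, 0), 1), "length mismatch")
})

test_that("metrics agree with a brute-force enumeration oracle", {
  brute <- function(y, s, thr) {
    tp <- fp <- fn <- tn <- 0
    for (i in seq_along(y)) {
      p <- s[i] > thr
      if (p && y[i] == 1) tp <- tp + 1
      if (p && y[i] == 0) fp <- fp + 1
      if (!p && y[i] == 1) fn <- fn + 1
      if (!p && y[i] == 0) tn <- tn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    pairs <- 0; wins <- 0
    for (i in which(y == 1)) for (j in which(y == 0)) {
      pairs <- pairs + 1
      wins <- wins + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    }
    list(acc = (tp + tn) / length(y), prec = prec, rec = rec,
         auc = if (pairs > 0 && any(y == 1) && any(y == 0)) wins / pairs
               else NA_real_)
  }
  withr::with_seed(77, {
    for (rep in 1:1000) {
      n <- sample(3:12, 1)
      y <- sample(0:1, n, replace = TRUE)
      s <- round(runif(n), 2)
      thr <- runif(1)
      m <- compute_metrics(y, s, thr)
      o <- brute(y, s, thr)
      expect_equal(m$accuracy, o$acc)
      expect_equal(m$precision, o$prec)
      expect_equal(m$recall, o$rec)
      if (!is.na(o$auc) && length(unique(y)) == 2) {
        expect_equal(m$auc, o$auc)
      }
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  withr::with_seed(83, {
    for (rep in 1:10) {
      y <- sample(0:1, 40, replace = TRUE)
      if (length(unique(y)) < 2) next
      s <- rnorm(40) + y
      ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                            direction = "<")))
      expect_equal(auc_score(y, s), ref)
    }
  })
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(31, {
    y <- sample(0:1, 50, replace = TRUE, prob = c(0.7, 0.3))
    s <- rnorm(50)
  })
  a0 <- auc_score(y, s)
  expect_equal(auc_score(y, exp(s)), a0)
  expect_equal(auc_score(y, 3 * s - 10), a0)
  expect_equal(auc_score(y, plogis(s)), a0)
})

test_that("F1 respects its harmonic-mean bounds and MCC its extremes", {
  withr::with_seed(41, {
    for (rep in 1:50) {
      y <- sample(0:1, 20, replace = TRUE)
      if (length(unique(y)) < 2) next
      m <- compute_metrics(y, runif(20), 0.5)
      expect_lte(m$f1, 2 * m$precision + 1e-12)
      expect_lte(m$f1, 2 * m$recall + 1e-12)
      expect_gte(m$mcc, -1); expect_lte(m$mcc, 1)
    }
  })
})

test_that("precision-recall analysis behaves at its anchors", {
  y <- c(rep(1, 5), rep(0, 15))
  expect_equal(pr_curve(y, 20:1)$auprc, 1)
  withr::with_seed(51, {
    yr <- c(rep(1, 1000), rep(0, 4000))
    sr <- runif(5000)
  })
  expect_lt(abs(pr_curve(yr, sr)$auprc - 0.2), 0.03)
})

test_that("the bootstrap PR analysis brackets its own point estimate", {
  withr::with_seed(61, {
    y <- sample(0:1, 120, replace = TRUE, prob = c(0.8, 0.2))
    s <- rnorm(120) + 2 * y
  })
  pb <- pr_curve_bootstrap(y, s, n_boot = 100, seed = 4)
  expect_equal(pb$auprc, pr_curve(y, s)$auprc)
  expect_lte(pb$ci[1], pb$auprc)
  expect_gte(pb$ci[2], pb$auprc)
  expect_length(pb$boot_auprc, 100)
  expect_true(all(pb$curve$lo <= pb$curve$hi))
  expect_error(pr_curve_bootstrap(y, s, n_boot = 1), "n_boot")
})

test_that("repeated random-split evaluation averages and reproduces", {
  b <- blob_data(n = 100, d = 4, sep = 5, prevalence = 0.3, seed = 6)
  ds <- list(X = b$X, labels = b$y)
  pipeline <- function(ds, tr, te, seed) {
    fit <- train_svm(ds$X[tr, ], ds$labels[tr])
    predict(fit, ds$X[te, ])
  }
  r1 <- repeated_random_split_eval(ds, pipeline, n_iter = 5, seed = 9,
                                   threshold = 0)
  expect_equal(unname(r1$mean["f1"]), mean(r1$per_iteration$f1))
  expect_equal(unname(r1$mean["auc"]), mean(r1$per_iteration$auc))
  r2 <- repeated_random_split_eval(ds, pipeline, n_iter = 5, seed = 9,
                                   threshold = 0)
  expect_identical(r1, r2)
  bad <- function(ds, tr, te, seed) {
    if (length(te) > 0) stop("boom")
    numeric(0)
  }
  expect_error(
    repeated_random_split_eval(ds, bad, n_iter = 3, seed = 9),
    "iteration 1")
})

test_that("lifespan extension rates follow the percent-change formula", {
  expect_identical(lifespan_extension_rate(26.39, 22.15), 19.1)
  expect_identical(lifespan_extension_rate(19.52, 22.15), -11.9)
  expect_identical(lifespan_extension_rate(22.15, 22.15), 0)
  expect_identical(lifespan_extension_rate(23.37, 22.15), 5.5)
  expect_error(lifespan_extension_rate(20, 0), "positive")
})
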