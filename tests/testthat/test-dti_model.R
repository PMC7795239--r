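# preprocessing, network training, cross-validation and metrics

small_dti <- function(seed = 81, n_pairs = 600, margin = 0.4) {
  generate_dti_dataset(n_drugs = 50, n_targets = 50, n_pairs = n_pairs,
                       drug_dim = 15, target_dim = 25, margin = margin,
                       seed = seed)
}

test_that("preprocessor standardizes on training data and PCA is orthonormal", {
  d <- small_dti()
  pp <- fit_preprocessor(d$features, n_components = 40)
  Z <- sweep(sweep(d$features, 2, pp$mu), 2, pp$sd, "/")
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_lt(max(abs(crossprod(pp$rotation) - diag(40))), 1e-10)
  expect_true(all(diff(pp$sdev) <= 1e-12))   # explained variance nonincreasing

  # full-rank PCA is an isometry of the standardized features
  ppf <- fit_preprocessor(d$features, n_components = 40 * 100)  # clipped
  Xp <- apply_preprocessor(ppf, d$features)
  i <- 1:20
  expect_equal(as.matrix(dist(Xp[i, ])),
               as.matrix(dist(Z[i, ] %*% ppf$rotation %*% t(ppf$rotation))),
               tolerance = 1e-8)
  expect_equal(as.matrix(dist(Xp[i, ])), as.matrix(dist(Z[i, ])), tolerance = 1e-8)
})

test_that("zero-variance features get a floored scale", {
  X <- cbind(rnorm(20), rep(3, 20))
  pp <- fit_preprocessor(X, 2)
  expect_equal(pp$sd[2], 1e-8)
  expect_true(all(is.finite(apply_preprocessor(pp, X))))
})

test_that("compiled and reference forward passes agree", {
  set.seed(82)
  X <- matrix(rnorm(30 * 12), 30, 12)
  net <- gwgendrug:::.mlp_init(c(12, 9, 6, 1))
  p_r <- drop(gwgendrug:::.mlp_forward(net, X)$A[[4]])
  p_c <- drop(gwgendrug:::.cpp_mlp_predict(net$W, net$b, X))
  expect_equal(p_c, p_r, tolerance = 1e-12)
})

test_that("reference backward pass matches the numerical gradient", {
  set.seed(83)
  X <- matrix(rnorm(15 * 6), 15, 6)
  y <- rbinom(15, 1, 0.5)
  net <- gwgendrug:::.mlp_init(c(6, 5, 3, 1))
  fwd <- gwgendrug:::.mlp_forward(net, X)
  gr <- gwgendrug:::.mlp_backward(net, fwd, y, 0)
  loss_at <- function(n) {
    p <- drop(gwgendrug:::.mlp_forward(n, X)$A[[4]])
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  eps <- 1e-6
  for (l in 1:3) {
    for (idx in list(c(1, 1), c(2, 1))) {
      n2 <- net
      n2$W[[l]][idx[1], idx[2]] <- n2$W[[l]][idx[1], idx[2]] + eps
      num <- (loss_at(n2) - loss_at(net)) / eps
      expect_equal(gr$W[[l]][idx[1], idx[2]], num, tolerance = 1e-4)
    }
  }
})

test_that("training separates a separable task and starts uninformative", {
  d <- small_dti(seed = 84, n_pairs = 800)
  pp <- fit_preprocessor(d$features, 40)
  X <- apply_preprocessor(pp, d$features)
  y <- d$pairs$label
  cfg <- dti_config(hidden = c(32, 16), dropout = 0.2, learning_rate = 3e-3,
                    epochs = 60, batch_size = 50, patience = 15,
                    n_components = 40, seed = 3)
  m <- train_dnn(X[1:600, ], y[1:600], X[601:800, ], y[601:800], cfg)
  expect_equal(m$history$train_loss[1], log(2), tolerance = 0.1)
  expect_gte(max(m$history$val_accuracy), 0.95)
  expect_lte(nrow(m$history), 60)

  # deterministic given the seed: bit-identical history and weights
  m2 <- train_dnn(X[1:600, ], y[1:600], X[601:800, ], y[601:800], cfg)
  expect_identical(m$history, m2$history)
  expect_identical(m$net, m2$net)

  # inference has no dropout: repeated passes identical
  p1 <- predict(m, X[601:800, ])
  p2 <- predict(m, X[601:800, ])
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))

  expect_error(train_dnn(X[1:10, ], rep(1, 10), X[11:12, ], y[11:12], cfg),
               "single class")
})

test_that("cross-validation reports ten folds plus summary rows", {
  d <- small_dti(seed = 85, n_pairs = 500)
  cfg <- dti_config(hidden = c(16, 8), dropout = 0.2, learning_rate = 3e-3,
                    epochs = 15, batch_size = 50, patience = 15,
                    n_components = 30, cv_folds = 10, seed = 4)
  cv <- cross_validate(d$features, d$pairs$label, cfg)
  expect_equal(nrow(cv$report), 12L)
  expect_equal(cv$report$fold, c(as.character(1:10), "Average", "Standard deviation"))
  folds <- cv$report[1:10, ]
  expect_equal(cv$report$testing_accuracy[11], mean(folds$testing_accuracy),
               tolerance = 1e-12)
  expect_equal(cv$report$validation_loss[12], sd(folds$validation_loss),
               tolerance = 1e-12)
  expect_equal(cv$best_fold, which.max(folds$testing_accuracy))
  # the held-out test quarter (stratified per class, so up to rounding)
  expect_lte(abs(length(cv$test_indices) - 0.25 * 500), 2)
})

test_that("evaluation metrics, ROC and AUC behave as defined", {
  labs <- c(rep(1, 6), rep(0, 6))
  perfect <- c(runif(6, 0.8, 1), runif(6, 0, 0.2))
  ev <- evaluate_predictions(perfect, labs)
  expect_equal(ev$auc, 1)
  expect_equal(ev$tpr, 1)
  expect_equal(ev$fpr, 0)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$roc$fpr[1], 0); expect_equal(ev$roc$tpr[1], 0)
  expect_equal(utils::tail(ev$roc$fpr, 1), 1)
  expect_equal(utils::tail(ev$roc$tpr, 1), 1)
  expect_true(all(diff(ev$roc$tpr) >= 0) && all(diff(ev$roc$fpr) >= 0))

  expect_error(evaluate_predictions(runif(5), rep(1, 5)), "single class")

  # AUC equals the normalized Mann-Whitney U statistic
  set.seed(86)
  for (r in 1:10) {
    n1 <- sample(5:15, 1); n0 <- sample(5:15, 1)
    s <- c(rnorm(n1, 0.6, 0.3), rnorm(n0, 0.4, 0.3))
    y <- c(rep(1, n1), rep(0, n0))
    ev <- evaluate_predictions(s, y)
    u <- sum(rank(s)[y == 1]) - n1 * (n1 + 1) / 2
    expect_equal(ev$auc, u / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(87)
  y <- rbinom(200, 1, 0.5)
  s <- plogis(y * 0.8 + rnorm(200))
  ev <- evaluate_predictions(s, y)
  ref <- pROC::auc(pROC::roc(y, s, quiet = TRUE))
  expect_equal(ev$auc, as.numeric(ref), tolerance = 1e-10)
})

test_that("binding prediction respects thresholds and dimensions", {
  d <- small_dti(seed = 88, n_pairs = 400)
  pp <- fit_preprocessor(d$features, 30)
  X <- apply_preprocessor(pp, d$features)
  cfg <- dti_config(hidden = c(16, 8), dropout = 0.2, learning_rate = 3e-3,
                    epochs = 20, batch_size = 50, patience = 20,
                    n_components = 30, seed = 5)
  m <- train_dnn(X[1:300, ], d$pairs$label[1:300], X[301:400, ],
                 d$pairs$label[301:400], cfg)
  drugs <- d$drug_features[1:5, ]
  tgts <- d$target_features[1:4, ]
  pb <- predict_bindings(m, pp, drugs, tgts, threshold = 0)
  expect_equal(nrow(pb), 20L)
  expect_true(all(pb$bound))
  pb1 <- predict_bindings(m, pp, drugs, tgts, threshold = max(pb$probability) + 1e-9)
  expect_false(any(pb1$bound))
  expect_error(predict_bindings(m, pp, drugs[, 1:5], tgts), "dimension")
})
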