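# Drug-target interaction classifier: concatenated drug+target descriptors
# are standardized, reduced by PCA, and classified by a fully connected
# network (input 618, hidden 512/256/128/64 with ReLU and dropout 0.4,
# sigmoid output) trained with Adam on binary cross-entropy. The forward and
# backward passes are vectorised over minibatches so all heavy lifting is
# BLAS matrix multiplication.

#' DTI model configuration
#'
#' Defaults follow the reference architecture: four hidden layers of 512,
#' 256, 128 and 64 ReLU units behind a 618-dimensional input, dropout 0.4
#' after each hidden layer, sigmoid output, Adam at learning rate 1e-4,
#' 100 epochs, batch size 100, a one-quarter test split and ten-fold
#' cross-validation. Early stopping monitors validation loss with patience 10
#' and restores the best weights.
#'
#' @param hidden Hidden layer widths.
#' @param dropout Dropout rate in \\[0, 1).
#' @param learning_rate Adam step size (> 0).
#' @param epochs,batch_size Training schedule.
#' @param patience Early-stopping patience in epochs (`Inf` to disable).
#' @param n_components PCA output dimension (clipped to the available rank).
#' @param test_fraction Held-out test fraction.
#' @param cv_folds Number of cross-validation folds.
#' @param seed Integer seed controlling initialisation, shuffling, dropout
#'   and data splits.
#' @return Configuration list of class `"dti_config"`.
#' @export
dti_config <- function(hidden = c(512, 256, 128, 64), dropout = 0.4,
                       learning_rate = 1e-4, epochs = 100, batch_size = 100,
                       patience = 10, n_components = 618,
                       test_fraction = 0.25, cv_folds = 10, seed = 1L) {
  if (any(hidden < 1)) stopf("layer sizes must be >= 1")
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0,1)")
  if (learning_rate <= 0) stopf("learning_rate must be > 0")
  structure(list(hidden = hidden, dropout = dropout,
                 learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, patience = patience,
                 n_components = n_components, test_fraction = test_fraction,
                 cv_folds = cv_folds, seed = as.integer(seed)),
            class = "dti_config")
}

#' Fit the feature preprocessor (standardization + PCA) on training data
#'
#' Per-feature means and standard deviations come from the training set only
#' (zero-variance features get a floored sd of 1e-8 with a logged warning);
#' PCA is fitted on the standardized training features. At full rank the PCA
#' rotation is an orthogonal change of basis.
#'
#' @param features Training feature matrix (pairs x features).
#' @param n_components Requested PCA dimension; clipped to
#'   `min(nrow, ncol)` with a warning if larger.
#' @return Object of class `"dti_preprocessor"`.
#' @export
fit_preprocessor <- function(features, n_components = 618) {
  features <- as.matrix(features)
  if (nrow(features) == 0) stopf("empty training set")
  mu <- colMeans(features)
  sd <- apply(features, 2, stats::sd)
  if (any(sd < 1e-8)) {
    gw_log("warn", "%d zero-variance feature(s); sd floored at 1e-8", sum(sd < 1e-8))
    sd[sd < 1e-8] <- 1e-8
  }
  max_comp <- min(nrow(features), ncol(features))
  if (n_components > max_comp) {
    gw_log("warn", "n_components %d clipped to %d", n_components, max_comp)
    n_components <- max_comp
  }
  Z <- sweep(sweep(features, 2, mu), 2, sd, "/")
  pca <- stats::prcomp(Z, center = FALSE, scale. = FALSE, rank. = n_components)
  structure(list(mu = mu, sd = sd, rotation = pca$rotation,
                 sdev = pca$sdev, n_components = n_components),
            class = "dti_preprocessor")
}

#' Apply a fitted preprocessor
#'
#' @param preproc A [fit_preprocessor()] object.
#' @param features Feature matrix with the same columns as the training set.
#' @return Matrix of `n_components` PCA coordinates.
#' @export
apply_preprocessor <- function(preproc, features) {
  features <- as.matrix(features)
  if (ncol(features) != length(preproc$mu)) {
    stopf("feature dimension %d does not match preprocessor (%d)",
          ncol(features), length(preproc$mu))
  }
  Z <- sweep(sweep(features, 2, preproc$mu), 2, preproc$sd, "/")
  Z %*% preproc$rotation
}

# ---- multilayer perceptron internals ---------------------------------------

.mlp_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], 0, sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b, sizes = sizes)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# forward pass; training=TRUE applies inverted dropout to hidden activations
.mlp_forward <- function(net, X, dropout = 0, training = FALSE) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  masks <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    if (l < L) {
      Z[Z < 0] <- 0                       # ReLU
      if (training && dropout > 0) {
        m <- matrix(stats::runif(length(Z)) >= dropout, nrow(Z), ncol(Z)) / (1 - dropout)
        Z <- Z * m
        masks[[l]] <- m
      }
    } else {
      Z <- .sigmoid(Z)
    }
    A[[l + 1L]] <- Z
  }
  list(A = A, masks = masks)
}

.bce <- function(phat, y) {
  phat <- pmin(pmax(phat, 1e-7), 1 - 1e-7)
  -mean(y * log(phat) + (1 - y) * log(1 - phat))
}

# gradients of mean BCE; sigmoid output makes delta_out = (phat - y)/n
.mlp_backward <- function(net, fwd, y, dropout) {
  L <- length(net$W)
  n <- length(y)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- (fwd$A[[L + 1L]] - y) / n
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fwd$A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(net$W[[l]])
      act <- fwd$A[[l]]
      delta[act <= 0] <- 0               # ReLU derivative (mask folded into act)
      if (!is.null(fwd$masks[[l - 1L]])) delta <- delta * fwd$masks[[l - 1L]]
    }
  }
  list(W = gW, b = gb)
}

# ---- public training interface ---------------------------------------------

#' Train the DTI network
#'
#' Minimises mean binary cross-entropy by Adam over shuffled minibatches
#' (compiled training loop; all randomness comes from R's RNG, so runs are
#' reproducible from the seed). Dropout is active only during training. The
#' history records the running minibatch training loss/accuracy per epoch and
#' a full validation pass; early stopping monitors validation loss and
#' restores the best parameters.
#'
#' @param x_train,y_train Training features (already preprocessed) and 0/1
#'   labels; both classes must be present.
#' @param x_val,y_val Validation data for early stopping and the history.
#' @param config A [dti_config()].
#' @param seed Overrides `config$seed` (used by cross-validation to give each
#'   fold its own stream).
#' @return Object of class `"dti_model"`: the network, a per-epoch `history`
#'   data frame and `best_epoch`.
#' @export
train_dnn <- function(x_train, y_train, x_val, y_val, config = dti_config(),
                      seed = NULL) {
  x_train <- as.matrix(x_train); x_val <- as.matrix(x_val)
  y_train <- as.numeric(y_train); y_val <- as.numeric(y_val)
  if (length(unique(y_train)) < 2) stopf("training labels contain a single class")
  if (nrow(x_train) == 0 || nrow(x_val) == 0) stopf("empty training or validation set")
  set.seed(seed %||% config$seed)
  res <- .cpp_mlp_train(x_train, y_train, x_val, y_val,
                        as.integer(config$hidden), config$dropout,
                        config$learning_rate, as.integer(config$epochs),
                        as.integer(config$batch_size), config$patience)
  if (res$best_epoch < nrow(res$history)) {
    gw_log("info", "early stop after epoch %d (best epoch %d)",
           nrow(res$history), res$best_epoch)
  }
  structure(list(net = list(W = res$W, b = res$b),
                 history = res$history, best_epoch = res$best_epoch,
                 config = config),
            class = "dti_model")
}

#' Predict binding probabilities
#'
#' Inference runs with dropout disabled and is deterministic.
#'
#' @param object A [train_dnn()] model.
#' @param x Preprocessed feature matrix.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.dti_model <- function(object, x, ...) {
  drop(.cpp_mlp_predict(object$net$W, object$net$b, as.matrix(x)))
}

# stratified index split: returns indices of the held-out part
.stratified_holdout <- function(labels, fraction) {
  unlist(lapply(unique(labels), function(cl) {
    i <- which(labels == cl)
    sample(i, round(length(i) * fraction))
  }), use.names = FALSE)
}

# stratified fold ids in 1..k
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    i <- sample(which(labels == cl))
    fold[i] <- rep_len(seq_len(k), length(i))
  }
  fold
}

#' Ten-fold cross-validation of the DTI model
#'
#' Splits off a stratified test quarter, fits the preprocessor on the
#' remaining training data, runs stratified k-fold cross-validation on it
#' (each fold trains on the other k-1 and validates on itself with early
#' stopping), and evaluates every fold model on the common test quarter. The
#' fold with the highest testing accuracy is retained as the working model.
#'
#' @param features Raw feature matrix (pairs x features).
#' @param labels 0/1 binding labels.
#' @param config A [dti_config()].
#' @return Object of class `"dti_cv"`: `report` (one row per fold plus
#'   `Average` and `Standard deviation` rows, accuracies in percent),
#'   `best_fold`, `model`, `preprocessor`, `test_indices`.
#' @export
cross_validate <- function(features, labels, config = dti_config()) {
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  k <- config$cv_folds
  if (length(labels) < 2 * k) stopf("need at least %d samples for %d-fold CV", 2 * k, k)
  set.seed(config$seed)
  test_idx <- sort(.stratified_holdout(labels, config$test_fraction))
  tr_idx <- setdiff(seq_along(labels), test_idx)
  if (length(unique(labels[tr_idx])) < 2) stopf("training data contains a single class")
  preproc <- fit_preprocessor(features[tr_idx, , drop = FALSE], config$n_components)
  X_tr <- apply_preprocessor(preproc, features[tr_idx, , drop = FALSE])
  X_te <- apply_preprocessor(preproc, features[test_idx, , drop = FALSE])
  y_tr <- labels[tr_idx]
  y_te <- labels[test_idx]
  fold <- .stratified_folds(y_tr, k)
  if (any(tabulate(fold, k) < 2)) stopf("too few samples to stratify %d folds", k)
  rows <- vector("list", k)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    va <- fold == f
    m <- train_dnn(X_tr[!va, , drop = FALSE], y_tr[!va],
                   X_tr[va, , drop = FALSE], y_tr[va],
                   config, seed = config$seed + f)
    p_va <- predict(m, X_tr[va, , drop = FALSE])
    p_te <- predict(m, X_te)
    rows[[f]] <- data.frame(
      fold = as.character(f),
      validation_loss = .bce(p_va, y_tr[va]),
      validation_accuracy = 100 * mean((p_va >= 0.5) == (y_tr[va] == 1)),
      testing_loss = .bce(p_te, y_te),
      testing_accuracy = 100 * mean((p_te >= 0.5) == (y_te == 1)),
      stringsAsFactors = FALSE)
    models[[f]] <- m
    gw_log("info", "fold %d: testing accuracy %.2f%%", f, rows[[f]]$testing_accuracy)
  }
  rep_df <- do.call(rbind, rows)
  num <- rep_df[, -1]
  rep_df <- rbind(rep_df,
                  cbind(fold = "Average", as.data.frame(as.list(colMeans(num)))),
                  cbind(fold = "Standard deviation",
                        as.data.frame(as.list(apply(num, 2, stats::sd)))))
  best_fold <- which.max(num$testing_accuracy)
  structure(list(report = rep_df, best_fold = best_fold,
                 model = models[[best_fold]], preprocessor = preproc,
                 test_indices = test_idx),
            class = "dti_cv")
}

#' @export
print.dti_cv <- function(x, ...) {
  cat("DTI cross-validation (best fold:", x$best_fold, ")\n")
  print(x$report, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Classification metrics, ROC curve and AUC
#'
#' Confusion counts are taken at probability threshold 0.5; the ROC curve is
#' a threshold sweep over the unique scores (anchored at (0,0) and (1,1))
#' and the AUC its trapezoidal area.
#'
#' @param scores Predicted probabilities.
#' @param labels 0/1 labels (both classes required).
#' @return Object of class `"dti_metrics"`: `tp`, `tn`, `fp`, `fn`, `tpr`,
#'   `specificity`, `fpr`, `accuracy`, `loss`, `roc` (data frame), `auc`.
#' @export
evaluate_predictions <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  if (length(unique(labels)) < 2) stopf("labels contain a single class; AUC undefined")
  pred <- scores >= 0.5
  tp <- sum(pred & labels == 1); fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0); fp <- sum(pred & labels == 0)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  keep <- c(diff(s) != 0, TRUE)      # last score in each tied block
  tpr <- c(0, cumsum(y == 1)[keep] / n_pos, 1)
  fpr <- c(0, cumsum(y == 0)[keep] / n_neg, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 tpr = tp / (tp + fn), specificity = tn / (tn + fp),
                 fpr = fp / (tn + fp),
                 accuracy = (tp + tn) / length(labels),
                 loss = .bce(scores, labels),
                 roc = data.frame(fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "dti_metrics")
}

#' @export
print.dti_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f | TPR %.4f | specificity %.4f | AUC %.4f | loss %.4f\n",
              x$accuracy, x$tpr, x$specificity, x$auc, x$loss))
  invisible(x)
}

#' Score all drug-target pairs and call bindings
#'
#' @param model A trained [train_dnn()] model.
#' @param preproc The matching [fit_preprocessor()].
#' @param drug_features Drug descriptor matrix (rownames = drug ids).
#' @param target_features Target descriptor matrix (rownames = target ids).
#' @param threshold Binding probability threshold (default 0.5).
#' @return Data frame `drug`, `target`, `probability`, `bound`, all pairs.
#' @export
predict_bindings <- function(model, preproc, drug_features, target_features,
                             threshold = 0.5) {
  drug_features <- as.matrix(drug_features)
  target_features <- as.matrix(target_features)
  nd <- nrow(drug_features); nt <- nrow(target_features)
  di <- rep(seq_len(nd), times = nt)
  ti <- rep(seq_len(nt), each = nd)
  feats <- cbind(drug_features[di, , drop = FALSE], target_features[ti, , drop = FALSE])
  prob <- predict(model, apply_preprocessor(preproc, feats))
  data.frame(drug = rownames(drug_features)[di],
             target = rownames(target_features)[ti],
             probability = prob,
             bound = prob >= threshold,
             stringsAsFactors = FALSE)
}
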