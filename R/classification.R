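# Classifier training and evaluation. Labels follow the convention
# cancerous = +1 (positive class), healthy = -1.

#' Convert class labels to the +1/-1 convention
#'
#' @param labels Character (`"cancerous"`/`"healthy"`) or numeric +1/-1.
#' @return Integer vector of +1/-1.
#' @export
as_signed_label <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(-1, 1)))
      stop("numeric labels must be +1/-1", call. = FALSE)
    return(as.integer(labels))
  }
  if (!all(labels %in% c("cancerous", "healthy")))
    stop("labels must be 'cancerous' or 'healthy'", call. = FALSE)
  ifelse(labels == "cancerous", 1L, -1L)
}

# Split a feature data.frame into X matrix and y (+1/-1); feature columns
# are everything numeric except id/label bookkeeping.
design_matrix <- function(data) {
  if (is.data.frame(data)) {
    drop_cols <- intersect(c("id", "label"), names(data))
    y <- if ("label" %in% names(data)) as_signed_label(data$label) else NULL
    X <- as.matrix(data[setdiff(names(data), drop_cols)])
  } else {
    stop("`data` must be a data.frame of features", call. = FALSE)
  }
  storage.mode(X) <- "double"
  list(X = X, y = y)
}

fit_scaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1   # constant columns pass through
  list(center = ctr, scale = scl)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

check_two_classes <- function(y) {
  if (is.null(y) || anyNA(y))
    stop("training data must carry labels", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training data contains a single class", call. = FALSE)
  if (min(table(y)) < 2L)
    stop("need at least 2 examples per class", call. = FALSE)
}

#' Train a soft-margin linear SVM
#'
#' Features are z-scored with statistics learned on the training data only;
#' the SVM uses a linear kernel with cost `C = 1` and solver tolerance
#' 1e-3. The decision rule is `sign(<u, p> + b)` with the documented
#' tie-break: a point exactly on the hyperplane is classified cancerous
#' (+1).
#'
#' @param data Feature data.frame (as from [extract_feature_table()]) with a
#'   `label` column, or any data.frame whose non-`id`/`label` columns are
#'   numeric features.
#' @param cost Soft-margin penalty C (default 1).
#' @param tolerance Solver termination tolerance (default 1e-3).
#' @return An `otex_classifier` with the fitted weights, bias, scaler and
#'   `support_vector_count`.
#' @export
train_svm <- function(data, cost = 1, tolerance = 1e-3) {
  d <- design_matrix(data)
  check_two_classes(d$y)
  scaler <- fit_scaler(d$X)
  Xs <- apply_scaler(d$X, scaler)
  fit <- e1071::svm(x = Xs, y = factor(d$y, levels = c(1, -1)),
                    kernel = "linear", cost = cost, tolerance = tolerance,
                    scale = FALSE)
  # explicit hyperplane: w = sum over SVs of coef * sv ; b = -rho, oriented
  # so that positive decision values mean the first factor level (+1)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients decision values toward the first class it encounters in
  # the data; flip if that is not the +1 class
  agree <- mean((drop(Xs %*% w) + b >= 0) ==
                  (stats::predict(fit, Xs) == "1"))
  if (agree < 0.5) { w <- -w; b <- -b }
  structure(list(kind = "linear_svm", weights = w, bias = b,
                 scaler = scaler, feature_names = colnames(d$X),
                 support_vector_count = sum(fit$nSV), model = fit),
            class = "otex_classifier")
}

#' Train a random forest with majority voting
#'
#' 100 bootstrap trees by default with per-split feature subsampling at
#' `floor(sqrt(d))`; prediction is the majority vote over trees, ties going
#' to the cancerous class (+1). Features are z-scored for interface parity
#' with the SVM (trees are scale-invariant, so this does not change the
#' fit).
#'
#' @inheritParams train_svm
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed for the bootstrap resampling.
#' @return An `otex_classifier`.
#' @export
train_random_forest <- function(data, n_trees = 100L, seed = 42L) {
  d <- design_matrix(data)
  check_two_classes(d$y)
  scaler <- fit_scaler(d$X)
  Xs <- apply_scaler(d$X, scaler)
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = Xs, y = factor(d$y, levels = c(1, -1)), ntree = n_trees,
    mtry = max(1L, floor(sqrt(ncol(Xs)))))
  structure(list(kind = "random_forest", model = fit, scaler = scaler,
                 feature_names = colnames(d$X), seed = as.integer(seed)),
            class = "otex_classifier")
}

#' @export
print.otex_classifier <- function(x, ...) {
  extra <- if (x$kind == "linear_svm")
    sprintf(", %d support vectors", x$support_vector_count)
  else sprintf(", %d trees", x$model$ntree)
  cat(sprintf("<otex_classifier> %s, %d features%s\n",
              x$kind, length(x$feature_names), extra))
  invisible(x)
}

#' Predict labels for new feature vectors
#'
#' @param object An `otex_classifier`.
#' @param newdata Feature data.frame or numeric matrix with the training
#'   feature columns.
#' @param ... Unused.
#' @return Integer vector of +1 (cancerous) / -1 (healthy).
#' @export
predict.otex_classifier <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) design_matrix(newdata)$X
       else as.matrix(newdata)
  if (ncol(X) != length(object$feature_names))
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 length(object$feature_names), ncol(X)), call. = FALSE)
  Xs <- apply_scaler(X, object$scaler)
  if (object$kind == "linear_svm") {
    f <- drop(Xs %*% object$weights) + object$bias
    unname(ifelse(f >= 0, 1L, -1L))
  } else {
    votes <- stats::predict(object$model, Xs, type = "vote")
    pos <- votes[, "1"]
    unname(ifelse(pos >= 0.5, 1L, -1L))
  }
}

#' Stratified k-fold cross-validation
#'
#' Splits each class separately into `k` folds of near-equal size (sizes
#' differ by at most one per class) with a fixed seed, retrains the model
#' from scratch inside every fold (including the feature scaler, so no test
#' statistics leak into training), and pools the out-of-fold predictions
#' into a single confusion matrix.
#'
#' @param data Labelled feature data.frame.
#' @param k Number of folds (default 5); every class must have at least `k`
#'   members.
#' @param model_kind `"linear_svm"` or `"random_forest"`.
#' @param seed Integer seed controlling the fold assignment (and the forest
#'   bootstrap).
#' @param ... Passed to the trainer.
#' @return List with `confusion` (a `confusion_matrix`), `metrics`,
#'   `fold_accuracy` (length-k vector), `folds` (fold id per row) and
#'   `predictions`.
#' @export
kfold_cv <- function(data, k = 5L, model_kind = c("linear_svm",
                     "random_forest"), seed = 42L, ...) {
  model_kind <- match.arg(model_kind)
  y <- as_signed_label(data$label)
  if (min(table(y)) < k)
    stop(sprintf("every class needs at least k = %d members", k),
         call. = FALSE)
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  preds <- integer(length(y))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    train <- data[fold != f, , drop = FALSE]
    test <- data[fold == f, , drop = FALSE]
    model <- if (model_kind == "linear_svm") train_svm(train, ...)
             else train_random_forest(train, seed = seed + f, ...)
    p <- predict(model, test)
    preds[fold == f] <- p
    fold_acc[f] <- mean(p == y[fold == f])
  }
  cm <- confusion(y, preds)
  list(confusion = cm, metrics = cm_metrics(cm), fold_accuracy = fold_acc,
       folds = fold, predictions = preds)
}
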