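#' @name learners
#' @title Classifiers for binary valence/arousal prediction
#' @description
#' Four learners are implemented in the package (no external learning
#' library is required): a linear soft-margin SVM trained by deterministic
#' full-batch subgradient descent on the hinge loss, a random (probability)
#' forest and a gradient-boosting machine both built on a compiled CART
#' grower, and a one-dimensional convolutional network (see [train_cnn()]).
#' All are deterministic given their seed. Inputs to the SVM are
#' standardized with statistics fitted on the training rows only.
NULL

as_binary01 <- function(y) {
  y <- dichotomize_if_needed(y)
  if (nlevels(droplevels(factor(y))) < 2L)
    stop("training set contains a single class")
  as.numeric(y == "high")
}

dichotomize_if_needed <- function(y) {
  if (is.factor(y)) factor(as.character(y), levels = c("low", "high"))
  else dichotomize(y)
}

#' Train a classifier
#'
#' @param kind One of `"svm"` (linear soft-margin SVM), `"rf"` (random
#'   forest, 500 trees), `"xgb"` (gradient boosting, 100 rounds of depth-3
#'   trees) or `"cnn"` (delegates to [train_cnn()]).
#' @param X Numeric matrix, rows = windows, columns = features.
#' @param y Binary labels: a low/high factor or raw 1-9 ratings.
#' @param seed Integer controlling every random choice of the learner.
#' @param config Named list of learner-specific overrides (e.g.
#'   `n_trees`, `nrounds`, `epochs`).
#' @return An object of class `emo_model` with a [predict()] method
#'   returning low/high factor labels (and probabilities via
#'   `type = "prob"`).
#' @export
train_classifier <- function(kind = c("svm", "rf", "xgb", "cnn"), X, y,
                             seed = 0L, config = list()) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in feature matrix")
  y01 <- as_binary01(y)
  if (nrow(X) != length(y01)) stop("X rows and labels differ in length")
  fit <- switch(kind,
    svm = fit_linear_svm(X, y01, seed, config),
    rf  = fit_forest(X, y01, seed, config),
    xgb = fit_boost(X, y01, seed, config),
    cnn = train_cnn(X, y01, do.call(cnn_architecture,
                                    c(config, list(seed = seed)))))
  structure(list(kind = kind, fit = fit, features = colnames(X)),
            class = "emo_model")
}

#' @export
predict.emo_model <- function(object, newdata, type = c("label", "prob"),
                              ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  prob <- switch(object$kind,
    svm = predict_linear_svm(object$fit, X),
    rf  = predict_forest(object$fit, X),
    xgb = predict_boost(object$fit, X),
    cnn = predict_cnn_prob(object$fit, X))
  if (type == "prob") return(prob)
  factor(ifelse(prob > 0.5, "high", "low"), levels = c("low", "high"))
}

#' Classification accuracy
#'
#' @param pred,truth Label vectors of equal length.
#' @return Fraction of agreements in \[0, 1\].
#' @export
accuracy <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) > 0L)
  mean(as.character(pred) == as.character(truth))
}

## ---- linear SVM (primal hinge, full-batch subgradient) ----

fit_linear_svm <- function(X, y01, seed, config) {
  lambda <- config$lambda %||% 1e-4
  iters <- config$iters %||% 500L
  mu <- colMeans(X)
  sg <- apply(X, 2L, sd)
  sg[sg == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sg, "/")
  yy <- ifelse(y01 == 1, 1, -1)
  set.seed(seed)
  w <- rnorm(ncol(X)) * 1e-3
  b <- 0
  for (t in seq_len(iters)) {
    eta <- 1 / (lambda * (t + 10))
    marg <- yy * (Xs %*% w + b)
    viol <- marg < 1
    n <- nrow(Xs)
    gw <- lambda * w -
      if (any(viol)) colSums(Xs[viol, , drop = FALSE] * yy[viol]) / n else 0
    gb <- if (any(viol)) -sum(yy[viol]) / n else 0
    w <- w - eta * gw
    b <- b - eta * gb
  }
  list(w = w, b = b, mu = mu, sg = sg)
}

predict_linear_svm <- function(fit, X) {
  Xs <- sweep(sweep(X, 2L, fit$mu), 2L, fit$sg, "/")
  score <- drop(Xs %*% fit$w + fit$b)
  1 / (1 + exp(-4 * score))  # monotone squash; decision boundary at 0
}

## ---- random forest (probability forest on CART trees) ----

fit_forest <- function(X, y01, seed, config) {
  n_trees <- config$n_trees %||% 500L
  mtry <- config$mtry %||% max(1L, floor(sqrt(ncol(X))))
  min_node <- config$min_node %||% 1L
  max_depth <- config$max_depth %||% 30L
  n <- nrow(X)
  set.seed(seed)
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    rows <- sample.int(n, n, replace = TRUE) - 1L
    trees[[t]] <- grow_tree_cpp(X, y01, rows, mtry, max_depth, min_node)
  }
  list(trees = trees)
}

predict_forest <- function(fit, X) {
  preds <- vapply(fit$trees, function(tr) tree_predict_cpp(tr, X),
                  numeric(nrow(X)))
  rowMeans(matrix(preds, nrow = nrow(X)))
}

## ---- gradient boosting (logistic loss, Newton leaf values) ----

fit_boost <- function(X, y01, seed, config) {
  nrounds <- config$nrounds %||% 100L
  eta <- config$eta %||% 0.1
  max_depth <- config$max_depth %||% 3L
  min_node <- config$min_node %||% 5L
  lambda <- config$lambda %||% 1
  n <- nrow(X)
  set.seed(seed)
  p0 <- mean(y01)
  p0 <- min(max(p0, 1e-6), 1 - 1e-6)
  f0 <- log(p0 / (1 - p0))
  F <- rep(f0, n)
  rows <- seq_len(n) - 1L
  trees <- vector("list", nrounds)
  leafvals <- vector("list", nrounds)
  for (t in seq_len(nrounds)) {
    p <- 1 / (1 + exp(-F))
    grad <- y01 - p
    hess <- p * (1 - p)
    tree <- grow_tree_cpp(X, grad, rows, ncol(X), max_depth, min_node)
    leaf <- tree_leaf_cpp(tree, X) + 1L
    g_leaf <- tapply(grad, leaf, sum)
    h_leaf <- tapply(hess, leaf, sum)
    vals <- numeric(length(tree$value))
    vals[as.integer(names(g_leaf))] <- g_leaf / (h_leaf + lambda)
    trees[[t]] <- tree
    leafvals[[t]] <- vals
    F <- F + eta * vals[leaf]
  }
  list(trees = trees, leafvals = leafvals, f0 = f0, eta = eta)
}

predict_boost <- function(fit, X) {
  F <- rep(fit$f0, nrow(X))
  for (t in seq_along(fit$trees)) {
    leaf <- tree_leaf_cpp(fit$trees[[t]], X) + 1L
    F <- F + fit$eta * fit$leafvals[[t]][leaf]
  }
  1 / (1 + exp(-F))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
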