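# Ridge-penalised logistic classification of training success with
# stratified random shuffling and pooled ROC/AUC.

# IRLS for L2-penalised logistic regression (intercept unpenalised).
# lambda = 1/C with the sklearn-style objective  sum logloss + lambda/2 |w|^2.
ridge_logistic <- function(x, y, lambda = 1, max_iter = 50, tol = 1e-10) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  X <- cbind(1, x)
  pen <- diag(c(0, rep(lambda, p)), p + 1)
  beta <- rep(0, p + 1)
  beta[1] <- {
    pr <- mean(y)
    pr <- min(max(pr, 1e-6), 1 - 1e-6)
    log(pr / (1 - pr))
  }
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - pen %*% beta
    H <- crossprod(X * W, X) + pen
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

#' Train a ridge logistic classifier and score held-out dogs
#'
#' Features are standardized with training-set statistics only
#' (zero-variance training features are dropped to zero), an L2-penalised
#' logistic model (fixed penalty, C-equivalent 1 by default) is fit on the
#' training dogs, and class-probability scores for the successful class are
#' returned for the test dogs.
#'
#' @param features numeric dogs x p matrix.
#' @param labels logical (TRUE = successful) or `"successful"` /
#'   `"non_successful"` per dog.
#' @param train_index,test_index disjoint row indices.
#' @param lambda ridge penalty (1/C).
#' @return Numeric vector of test scores in (0, 1).
#' @export
logistic_train_predict <- function(features, labels, train_index, test_index,
                                   lambda = 1) {
  features <- as.matrix(features)
  y <- if (is.logical(labels)) labels else labels == "successful" | labels == TRUE
  stopifnot(!length(intersect(train_index, test_index)))
  ytr <- y[train_index]
  if (all(ytr) || !any(ytr)) {
    stop("logistic_train_predict: training set contains a single class")
  }
  xtr <- features[train_index, , drop = FALSE]
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- Inf  # constant features carry no signal
  std <- function(m) sweep(sweep(m, 2, mu), 2, sdv, "/")
  beta <- ridge_logistic(std(xtr), ytr, lambda)
  xte <- std(features[test_index, , drop = FALSE])
  drop(1 / (1 + exp(-(beta[1] + xte %*% beta[-1]))))
}

# Class-stratified test indices: per-class counts by largest remainder
# (ties broken toward the larger class), matching a 25% test share.
stratified_test_split <- function(y, test_fraction) {
  idx1 <- which(y); idx0 <- which(!y)
  n_test <- round(test_fraction * length(y))
  base1 <- floor(test_fraction * length(idx1))
  base0 <- floor(test_fraction * length(idx0))
  rem <- n_test - base1 - base0
  f1 <- test_fraction * length(idx1) - base1
  f0 <- test_fraction * length(idx0) - base0
  while (rem > 0) {
    if (f1 > f0 || (f1 == f0 && length(idx1) > length(idx0))) {
      base1 <- base1 + 1; f1 <- -1
    } else {
      base0 <- base0 + 1; f0 <- -1
    }
    rem <- rem - 1
  }
  base1 <- max(1, min(base1, length(idx1) - 1))
  base0 <- max(1, min(base0, length(idx0) - 1))
  sort(c(sample(idx1, base1), sample(idx0, base0)))
}

#' ROC curve and AUC from scores and labels
#'
#' Threshold sweep over the unique scores; AUC by the trapezoid rule, which
#' with tied scores equals the Mann-Whitney statistic U/(n1 n2) with
#' half-credit for ties (the probability a random successful dog outscores a
#' random non-successful dog).
#'
#' @param scores numeric scores, higher = more likely successful.
#' @param labels logical (TRUE = successful) or `"successful"` /
#'   `"non_successful"`.
#' @return An object of class `roc_result`: list with `roc` (data.frame of
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.logical(labels)) labels else labels == "successful" | labels == TRUE
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("roc_auc: both classes must be present")
  stopifnot(length(scores) == length(y), all(is.finite(scores)))
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys); fp <- cumsum(!ys)
  last <- !duplicated(ss, fromLast = TRUE)  # one point per distinct score
  tpr <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  thr <- c(Inf, ss[last])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc, n_successful = n1, n_non_successful = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d successful vs %d non-successful)\n",
              x$auc, x$n_successful, x$n_non_successful))
  invisible(x)
}

#' Repeated stratified-shuffle evaluation of a feature set
#'
#' Each iteration draws a class-stratified train/test split (default 75/25,
#' the one-fold-of-four reading of four-fold cross-validation), fits the
#' ridge logistic model on the training dogs, and scores the test dogs.
#' Scores pooled across iterations yield one ROC and AUC; the mean of the
#' per-iteration AUCs is reported alongside.
#'
#' @param features dogs x p matrix.
#' @param labels outcome labels per dog.
#' @param n_iterations number of random splits (default 1000).
#' @param test_fraction test share (default 0.25).
#' @param lambda ridge penalty.
#' @param selector optional function(train_index) returning the feature
#'   columns to use, for nested (within-fold) feature selection; NULL uses
#'   all columns.
#' @return An object of class `classifier_result`: the pooled `roc_result`
#'   plus per-iteration scores, the mean per-iteration AUC, and settings.
#' @export
stratified_shuffle_eval <- function(features, labels, n_iterations = 1000,
                                    test_fraction = 0.25, lambda = 1,
                                    selector = NULL) {
  features <- as.matrix(features)
  y <- if (is.logical(labels)) labels else labels == "successful" | labels == TRUE
  stopifnot(sum(y) >= 2, sum(!y) >= 2)
  all_scores <- vector("list", n_iterations)
  all_labels <- vector("list", n_iterations)
  iter_auc <- rep(NA_real_, n_iterations)
  for (it in seq_len(n_iterations)) {
    test <- stratified_test_split(y, test_fraction)
    train <- setdiff(seq_along(y), test)
    cols <- if (is.null(selector)) seq_len(ncol(features)) else selector(train)
    if (!length(cols)) {  # nothing selected in this fold: uninformative scores
      sc <- rep(mean(y[train]), length(test))
    } else {
      sc <- logistic_train_predict(features[, cols, drop = FALSE], y,
                                   train, test, lambda)
    }
    all_scores[[it]] <- sc
    all_labels[[it]] <- y[test]
    if (any(y[test]) && !all(y[test])) {
      iter_auc[it] <- roc_auc(sc, y[test])$auc
    }
  }
  pooled <- roc_auc(unlist(all_scores), unlist(all_labels))
  structure(list(roc = pooled$roc, auc = pooled$auc,
                 mean_iteration_auc = mean(iter_auc, na.rm = TRUE),
                 scores = all_scores, labels = all_labels,
                 n_iterations = n_iterations, test_fraction = test_fraction,
                 lambda = lambda),
            class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf(
    "<classifier_result> pooled AUC = %.4f (mean per-iteration %.4f) over %d x %.0f%% splits\n",
    x$auc, x$mean_iteration_auc, x$n_iterations, 100 * x$test_fraction))
  invisible(x)
}

#' Compare the three predictive feature sets
#'
#' Runs [stratified_shuffle_eval()] on (1) the integrated behavioral score
#' at TP1, (2) periphery-edge FC at TP1, and (3) core-edge FC at TP1, and
#' returns the results keyed by feature-set name. An empty edge set yields a
#' result marked not applicable.
#'
#' @param edge_table an `edge_table` containing TP1.
#' @param behavior behavior data.frame with TP1 rows.
#' @param labels outcome labels per dog (see [group_difference_test()]).
#' @param periphery_edges,core_edges data.frames with columns `i`, `j`.
#' @param n_iterations,test_fraction,lambda see [stratified_shuffle_eval()].
#' @return Named list of `classifier_result` (or `NA` for empty sets) with
#'   names `behavior`, `periphery`, `core`.
#' @export
compare_feature_sets <- function(edge_table, behavior, labels,
                                 periphery_edges, core_edges,
                                 n_iterations = 1000, test_fraction = 0.25,
                                 lambda = 1) {
  dogs <- edge_table$dogs
  y <- check_labels(labels, dogs)
  N <- length(edge_table$region_labels)
  tp1 <- matrix(edge_table$values[, "TP1", ], nrow = length(dogs))
  feat <- list(
    behavior = matrix(ibs_by_dog(behavior, dogs, "TP1"), ncol = 1),
    periphery = if (!is.null(periphery_edges) && nrow(periphery_edges)) {
      tp1[, edge_ids(periphery_edges[, c("i", "j")], N), drop = FALSE]
    },
    core = if (!is.null(core_edges) && nrow(core_edges)) {
      tp1[, edge_ids(core_edges[, c("i", "j")], N), drop = FALSE]
    }
  )
  lapply(feat, function(f) {
    if (is.null(f) || !ncol(f)) {
      structure(list(auc = NA_real_, not_applicable = TRUE),
                class = "classifier_result")
    } else {
      stratified_shuffle_eval(f, y, n_iterations, test_fraction, lambda)
    }
  })
}
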