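#' Linear discriminant analysis (two classes, closed form)
#'
#' Pooled-covariance LDA with an optional ridge term for singular
#' covariances: weights w = (S + eps I)^{-1} (mu1 - mu0), intercept such
#' that the score s(x) = w'x + b is zero on the equal-posterior boundary
#' under the chosen priors. The positive class is the second factor level
#' (or the value 1 for 0/1 labels).
#'
#' @param X numeric matrix, patients x features.
#' @param y two-class labels.
#' @param ridge ridge epsilon added to the pooled covariance diagonal;
#'   default 1e-6 * trace(S)/d. Use 0 to disable.
#' @param priors `"estimated"` (class frequencies) or `"equal"`.
#' @return list of class `lda_model`: `weights`, `intercept`,
#'   `class_means`, `pooled_cov`, `priors`, `levels`.
#' @export
fit_lda <- function(X, y, ridge = NULL, priors = c("estimated", "equal")) {
  priors <- match.arg(priors)
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2)
    stop("fit_lda: both classes must be present")
  y <- droplevels(y)
  d <- ncol(X)
  X0 <- X[y == levels(y)[1], , drop = FALSE]
  X1 <- X[y == levels(y)[2], , drop = FALSE]
  mu0 <- colMeans(X0); mu1 <- colMeans(X1)
  S <- (crossprod(sweep(X0, 2, mu0)) + crossprod(sweep(X1, 2, mu1))) /
    (nrow(X) - 2)
  if (is.null(ridge)) ridge <- 1e-6 * sum(diag(S)) / d
  Sr <- S + diag(ridge, d)
  w <- tryCatch(solve(Sr, mu1 - mu0),
                error = function(e)
                  stop("fit_lda: singular pooled covariance; ",
                       "supply a positive ridge epsilon"))
  p1 <- if (priors == "equal") 0.5 else mean(y == levels(y)[2])
  b <- -sum(w * (mu0 + mu1)) / 2 + log(p1 / (1 - p1))
  structure(list(weights = w, intercept = b,
                 class_means = rbind(mu0, mu1), pooled_cov = Sr,
                 priors = c(1 - p1, p1), levels = levels(y)),
            class = "lda_model")
}

#' @rdname fit_lda
#' @param model a fitted `lda_model`.
#' @param newdata matrix of features.
#' @return `predict_lda()`: numeric discriminant scores (positive favors
#'   the positive class).
#' @export
predict_lda <- function(model, newdata) {
  newdata <- as.matrix(newdata)
  as.vector(newdata %*% model$weights + model$intercept)
}

#' ROC curve, AUC and the accuracy-maximizing operating point
#'
#' Thresholds at the distinct scores (descending) with +/-Inf sentinels; a
#' case is predicted positive when score >= threshold. AUC by the
#' trapezoid rule over (FPR, TPR); the operating point maximizes overall
#' accuracy, ties broken toward the higher sensitivity. Precision at an
#' operating point predicting no positives is reported as NA.
#'
#' @param scores numeric scores (higher = more positive).
#' @param y two-class labels; positive = second level / value 1.
#' @return list of class `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`,
#'   `oop_threshold`, `oop_metrics` (accuracy, sensitivity, specificity,
#'   precision).
#' @export
roc_curve <- function(scores, y) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2)
    stop("roc_curve: both classes must be present")
  y <- droplevels(y)
  pos <- y == levels(y)[2]
  np <- sum(pos); nn <- sum(!pos)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tp <- vapply(thr, function(t) sum(scores[pos] >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(scores[!pos] >= t), numeric(1))
  tpr <- tp / np; fpr <- fp / nn
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  acc <- (tp + (nn - fp)) / (np + nn)
  best <- which(acc == max(acc))
  best <- best[which.max(tpr[best])]      # tie toward sensitivity
  prec <- if (tp[best] + fp[best] > 0) tp[best] / (tp[best] + fp[best])
          else NA_real_
  structure(list(
    thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
    oop_threshold = thr[best],
    oop_metrics = c(accuracy = acc[best], sensitivity = tpr[best],
                    specificity = 1 - fpr[best], precision = prec)),
    class = "roc_result")
}
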