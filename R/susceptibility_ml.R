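#' PCA projection of pair-correlation vectors
#'
#' Mean-centered principal component analysis; the first three component
#' scores are returned for visualization together with their contribution
#' ratios (eigenvalue over total variance). If the data rank is below 3, the
#' missing components are zero-padded.
#'
#' @param vectors Rats x features matrix (complete, post-imputation; >= 4
#'   rats).
#' @return A `pca_result` list: `scores` (rats x 3), `contribution_ratios`
#'   (length 3, non-increasing, summing to <= 1) and `rotation`.
#' @export
pca_project <- function(vectors) {
  vectors <- as.matrix(vectors)
  stopifnot(nrow(vectors) >= 4)
  pc <- stats::prcomp(vectors, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  k <- min(3, sum(ev > .Machine$double.eps * max(ev, 1)))
  scores <- matrix(0, nrow(vectors), 3,
                   dimnames = list(rownames(vectors), paste0("PC", 1:3)))
  ratios <- numeric(3)
  if (k > 0) {
    scores[, 1:k] <- pc$x[, 1:k]
    ratios[1:k] <- ev[1:k] / sum(ev)
  }
  structure(list(scores = scores, contribution_ratios = ratios,
                 rotation = pc$rotation),
            class = "pca_result")
}

#' Train a soft-margin linear SVM
#'
#' Features are z-scored internally (the weights and bias are reported back
#' on the original feature scale, in the original feature order) and a linear
#' SVM with cost `C` is fit. The decision value for a feature vector `x` is
#' `sum(weights * x) + bias`, positive for the first factor level of `labels`.
#'
#' @param vectors Rats x features matrix.
#' @param labels Two-class factor (or character) per rat.
#' @param C Soft-margin cost (default 1).
#' @return An `svm_result` list: `weights`, `bias`, `levels` and `model` (the
#'   underlying fit, used by [predict_svm()]).
#' @export
train_linear_svm <- function(vectors, labels, C = 1) {
  vectors <- as.matrix(vectors)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("need exactly two classes; got ", nlevels(labels))
  # drop zero-variance features from scaling (constant columns carry no signal)
  scale_ok <- apply(vectors, 2, stats::sd) > 0
  fit <- e1071::svm(x = vectors, y = labels, kernel = "linear", cost = C,
                    scale = scale_ok, type = "C-classification")
  w_scaled <- drop(t(fit$coefs) %*% fit$SV)
  weights <- stats::setNames(numeric(ncol(vectors)), colnames(vectors))
  bias <- -fit$rho
  sc <- fit$x.scale
  if (is.null(sc)) {
    weights[] <- w_scaled
  } else {
    # e1071 scales only the columns with scale_ok = TRUE
    ctr <- stats::setNames(numeric(ncol(vectors)), colnames(vectors))
    scl <- stats::setNames(rep(1, ncol(vectors)), colnames(vectors))
    ctr[scale_ok] <- sc$`scaled:center`
    scl[scale_ok] <- sc$`scaled:scale`
    weights[] <- w_scaled / scl
    bias <- bias - sum(w_scaled * ctr / scl)
  }
  # libsvm orients the decision function by order of class appearance in the
  # data; fix the convention to "positive decision value = first factor level"
  f <- drop(vectors %*% weights + bias)
  pred <- as.character(stats::predict(fit, vectors))
  anchor <- which.max(abs(f))
  if ((f[anchor] > 0) != (pred[anchor] == levels(labels)[1])) {
    weights <- -weights
    bias <- -bias
  }
  structure(list(weights = weights, bias = bias, levels = levels(labels),
                 model = fit),
            class = "svm_result")
}

#' Predict with a trained linear SVM
#'
#' @param svm An `svm_result` from [train_linear_svm()].
#' @param vectors Rats x features matrix.
#' @return Character vector of predicted labels.
#' @export
predict_svm <- function(svm, vectors) {
  as.character(stats::predict(svm$model, as.matrix(vectors)))
}

#' Leave-one-out cross-validated failure percentage
#'
#' For each rat, a linear SVM is retrained on the remaining `n - 1` rats
#' (features re-standardized within the training fold) and the held-out rat
#' is predicted; the failure percentage is `100 * misclassified / n` (always
#' a multiple of `100 / n`). A training fold reduced to a single class
#' predicts that fold's majority class.
#'
#' @inheritParams train_linear_svm
#' @return List with `failure_percent`, `n`, `predicted` and `actual`.
#' @export
loocv_failure <- function(vectors, labels, C = 1) {
  vectors <- as.matrix(vectors)
  labels <- as.character(labels)
  n <- nrow(vectors)
  stopifnot(n >= 3, length(unique(labels)) == 2)
  pred <- character(n)
  for (i in seq_len(n)) {
    tr_x <- vectors[-i, , drop = FALSE]
    tr_y <- labels[-i]
    if (length(unique(tr_y)) < 2) {
      tab <- table(tr_y)
      pred[i] <- names(tab)[which.max(tab)]
    } else {
      fit <- train_linear_svm(tr_x, tr_y, C = C)
      pred[i] <- predict_svm(fit, vectors[i, , drop = FALSE])
    }
  }
  list(failure_percent = 100 * sum(pred != labels) / n, n = n,
       predicted = pred, actual = labels)
}
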