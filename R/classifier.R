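#' Fit the multi-class Gaussian probabilistic classifier
#'
#' Models each class as a Gaussian with class-specific mean `m_k` and a
#' common covariance `S`, estimated as the *unweighted* mean of the per-class
#' sample covariances (denominator `n_k - 1`) and regularized by shrinkage
#' towards a scaled identity: `S = (1 - lambda) * S_raw + lambda * nu * I`,
#' with `nu` the mean of the diagonal of `S_raw`. Inverting the model by
#' Bayes' rule under a flat prior gives linear discriminants
#' `a_k(x) = w_k' x + w_k0` with `w_k = S^-1 m_k` and
#' `w_k0 = -1/2 m_k' S^-1 m_k`, and class posteriors
#' `P(k | x) = exp(a_k) / sum_j exp(a_j)`.
#'
#' @param X numeric matrix, trials x features.
#' @param labels class label per trial (any atomic type).
#' @param lambda shrinkage strength in \[0, 1\]; `lambda = 1` yields
#'   `S = nu * I` exactly. Conventional values: 0.05 for MEG features, 0.01
#'   for the two-dimensional gaze features.
#' @return an object of class `oculomem_classifier` with elements `means`
#'   (features x classes), `covariance` (shrunk `S`), `weights` (features x
#'   classes), `offsets`, `classes`, `lambda`, `nu`.
#' @export
fit_classifier <- function(X, labels, lambda = 0.05) {
  X <- as.matrix(X)
  if (nrow(X) != length(labels)) {
    abort("`labels` must have one entry per row of `X`.")
  }
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
    abort("`lambda` must lie in [0, 1].")
  }
  classes <- sort(unique(labels))
  K <- length(classes)
  if (K < 2) abort("need at least two classes.")
  p <- ncol(X)
  means <- matrix(0, p, K)
  S_raw <- matrix(0, p, p)
  for (k in seq_len(K)) {
    idx <- which(labels == classes[k])
    if (length(idx) < 2) {
      abort(sprintf("class '%s' has fewer than 2 trials.", classes[k]))
    }
    Xi <- X[idx, , drop = FALSE]
    means[, k] <- colMeans(Xi)
    Xi <- sweep(Xi, 2, means[, k])
    S_raw <- S_raw + crossprod(Xi) / (length(idx) - 1)
  }
  S_raw <- S_raw / K
  nu <- mean(diag(S_raw))
  S <- (1 - lambda) * S_raw + lambda * nu * diag(p)
  W <- solve(S, means)
  offsets <- -0.5 * colSums(means * W)
  structure(
    list(means = means, covariance = S, weights = W, offsets = offsets,
         classes = classes, lambda = lambda, nu = nu),
    class = "oculomem_classifier"
  )
}

#' Class posterior probabilities
#'
#' Evaluates `P(class = k | x) = exp(a_k) / sum_j exp(a_j)` with
#' `a_k = w_k' x + w_k0`. Computed with max-subtraction (log-sum-exp
#' stabilization), which leaves the result invariant to adding any constant
#' to all discriminants while avoiding overflow.
#'
#' @param model an [fit_classifier()] result.
#' @param x a feature vector, or a trials x features matrix.
#' @return a trials x classes matrix of probabilities; rows sum to 1.
#' @export
posterior <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(model$weights)) {
    abort(sprintf("`x` has %d features but the model expects %d.",
                  ncol(x), nrow(model$weights)))
  }
  a <- x %*% model$weights +
    matrix(model$offsets, nrow(x), length(model$offsets), byrow = TRUE)
  softmax_rows(a, model$classes)
}

softmax_rows <- function(a, classes = NULL) {
  a <- a - apply(a, 1, max)
  e <- exp(a)
  p <- e / rowSums(e)
  if (!is.null(classes)) colnames(p) <- as.character(classes)
  p
}

#' @export
print.oculomem_classifier <- function(x, ...) {
  cat(sprintf(
    "<oculomem_classifier> %d classes, %d features, shrinkage lambda = %g\n",
    length(x$classes), nrow(x$weights), x$lambda))
  invisible(x)
}

#' @export
predict.oculomem_classifier <- function(object, newdata, ...) {
  posterior(object, newdata)
}

#' Tidy a fitted probabilistic classifier
#'
#' One row per (class, feature) with the class mean and discriminant weight.
#'
#' @param x an `oculomem_classifier`.
#' @param ... unused.
#' @export
tidy.oculomem_classifier <- function(x, ...) {
  p <- nrow(x$weights)
  tibble::tibble(
    class = rep(as.character(x$classes), each = p),
    feature = rep(seq_len(p), times = length(x$classes)),
    mean = as.vector(x$means),
    weight = as.vector(x$weights)
  )
}

#' @rdname tidy.oculomem_classifier
#' @export
glance.oculomem_classifier <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    n_features = nrow(x$weights),
    lambda = x$lambda,
    nu = x$nu
  )
}
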