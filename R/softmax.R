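#' Fit the inner label-smoothed softmax-regression classifier
#'
#' Multinomial logistic regression trained by full-batch gradient descent on
#' the label-smoothed cross-entropy, the training loss of the classification
#' head.  Columns are standardized by training-set statistics (constant
#' columns get scale 1); fitting is deterministic (zero initialization).
#'
#' @param x n x d numeric matrix.
#' @param y integer labels in 1..C.
#' @param n_classes class count C.
#' @param epsilon label-smoothing parameter in \[0, 1).
#' @param learning_rate gradient-descent step size (on standardized inputs).
#' @param epochs number of full-batch iterations.
#' @return object of class `softmax_model`.
#' @export
fit_softmax <- function(x, y, n_classes, epsilon = 0.1,
                        learning_rate = 0.5, epochs = 150L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(y >= 1), all(y <= n_classes))
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  W <- cpp_softmax_fit(xs, as.integer(y), as.integer(n_classes),
                       epsilon, learning_rate, as.integer(epochs))
  structure(list(weights = W, center = ctr, scale = scl,
                 n_classes = as.integer(n_classes), epsilon = epsilon),
            class = "softmax_model")
}

standardize_like <- function(model, x) {
  sweep(sweep(as.matrix(x), 2, model$center), 2, model$scale, "/")
}

#' Predict class labels from a fitted softmax model
#'
#' @param object a `softmax_model`.
#' @param newdata matrix with the training columns.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... unused.
#' @return integer labels or an n x C probability matrix.
#' @export
predict.softmax_model <- function(object, newdata,
                                  type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- cpp_softmax_prob(object$weights, standardize_like(object, newdata))
  if (type == "prob") p else max.col(p, ties.method = "first")
}

#' Label-smoothed validation loss of a fitted softmax model
#'
#' @param model a `softmax_model`.
#' @param x,y validation data and integer labels.
#' @param epsilon smoothing used in the evaluated loss (defaults to the
#'   model's training value).
#' @return nonnegative scalar loss (mean over samples).
#' @export
softmax_loss <- function(model, x, y, epsilon = model$epsilon) {
  cpp_softmax_loss(model$weights, standardize_like(model, x),
                   as.integer(y), model$n_classes, epsilon)
}

# Analytic loss + gradient of the softmax head under label smoothing,
# in plain R. Kept independent of the C++ trainer so that finite-difference
# contracts check real mathematics, not one code path against itself.
# W is (d+1) x C with the first row the intercept.
softmax_head_loss_grad <- function(W, x, y, n_classes, epsilon) {
  xb <- cbind(1, as.matrix(x))
  n <- nrow(xb)
  z <- xb %*% W
  z <- z - apply(z, 1, max)
  p <- exp(z) / rowSums(exp(z))
  targets <- matrix(epsilon / n_classes, n, n_classes)
  targets[cbind(seq_len(n), y)] <- 1 - epsilon + epsilon / n_classes
  loss <- -sum(targets * log(pmax(p, 1e-300))) / n
  grad <- t(xb) %*% (p - targets) / n
  list(loss = loss, grad = grad)
}
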