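#' Manifold smoothness of node embeddings
#'
#' `1/2 * sum_q sum_{j in N(q)} ||h_q - h_j||^2 = trace(H^T L H)` with L the
#' unnormalized Laplacian `D - A_bin` of the binary support of the
#' adjacency. Penalizing this keeps embeddings of adjacent regions close.
#'
#' @param h Q x d node-embedding matrix (last graph layer's output).
#' @param a Q x Q adjacency; only its nonzero pattern is used.
#' @param form `"trace"` (default, used in training) or `"double_sum"`
#'   (the definitional form; both are equal and the identity is tested).
#' @return Nonnegative scalar.
#' @export
manifold_loss <- function(h, a, form = c("trace", "double_sum")) {
  form <- match.arg(form)
  h <- as.matrix(h)
  a <- as.matrix(a)
  if (nrow(h) != nrow(a)) stop("manifold_loss: H and A must share Q")
  abin <- (a != 0) * 1
  diag(abin) <- 0
  if (form == "trace") {
    lap <- graph_laplacian(abin)
    sum(diag(crossprod(h, lap %*% h)))
  } else {
    tot <- 0
    q <- nrow(a)
    for (i in seq_len(q)) {
      nb <- which(abin[i, ] != 0)
      for (j in nb) tot <- tot + sum((h[i, ] - h[j, ])^2)
    }
    tot / 2
  }
}

#' Unnormalized graph Laplacian of the binary support
#' @param a Q x Q adjacency; nonzero pattern defines edges.
#' @return Q x Q Laplacian `D - A_bin`.
#' @export
graph_laplacian <- function(a) {
  abin <- (as.matrix(a) != 0) * 1
  diag(abin) <- 0
  diag(rowSums(abin)) - abin
}

#' Mask sparsity / orthonormality penalty
#'
#' `lambda1 ||M||_1 + lambda2 ||M||_F^2 + lambda3 ||M M^T - I||_F`: the L1
#' and squared-Frobenius terms promote a sparse mask, while the third term
#' softly pushes the mask rows toward an orthonormal, basis-like
#' configuration.
#'
#' @param m Q x Q mask.
#' @param lambda1,lambda2,lambda3 Nonnegative regularization weights.
#' @return Nonnegative scalar.
#' @export
mask_penalty <- function(m, lambda1, lambda2, lambda3) {
  m <- as.matrix(m)
  e <- tcrossprod(m) - diag(nrow(m))
  lambda1 * sum(abs(m)) + lambda2 * sum(m^2) + lambda3 * sqrt(sum(e^2))
}

# Gradient of mask_penalty w.r.t. M. The Frobenius-norm term uses
# d||MM^T - I||_F/dM = 2 (MM^T - I) M / ||MM^T - I||_F, with subgradient 0
# at the (measure-zero) point where the norm vanishes.
mask_penalty_grad <- function(m, lambda1, lambda2, lambda3) {
  m <- as.matrix(m)
  e <- tcrossprod(m) - diag(nrow(m))
  nf <- sqrt(sum(e^2))
  g3 <- if (nf > 1e-12) 2 * (e %*% m) / nf else matrix(0, nrow(m), ncol(m))
  lambda1 * sign(m) + 2 * lambda2 * m + lambda3 * g3
}

#' Prediction error
#'
#' Mean squared error averaged over targets and subjects (regression) or
#' cross-entropy from logits (classification).
#'
#' @param yhat Predictions: numeric vector/matrix (regression) or logit
#'   matrix with one column per class (classification).
#' @param y Targets: numeric (regression) or integer class labels in
#'   `1..n_classes` (classification).
#' @param task `"regression"` or `"classification"`.
#' @return Nonnegative scalar.
#' @export
prediction_loss <- function(yhat, y, task = c("regression", "classification")) {
  task <- match.arg(task)
  if (task == "regression") {
    yhat <- as.matrix(yhat); y <- as.matrix(y)
    if (!all(dim(yhat) == dim(y)))
      stop("prediction_loss: shape mismatch between predictions and targets")
    mean((yhat - y)^2)
  } else {
    logits <- if (is.matrix(yhat)) yhat else matrix(yhat, nrow = 1)
    y <- as.integer(y)
    if (any(y < 1L | y > ncol(logits)))
      stop("prediction_loss: label outside the class set")
    lse <- apply(logits, 1, function(r) {
      mx <- max(r); mx + log(sum(exp(r - mx)))
    })
    mean(lse - logits[cbind(seq_along(y), y)])
  }
}

# Gradient of the per-subject prediction loss w.r.t. one subject's yhat,
# matching prediction_loss's batch-mean convention (caller divides by the
# batch size).
prediction_loss_grad <- function(yhat, y, task) {
  if (task == "regression") {
    2 * (yhat - y) / length(yhat)
  } else {
    p <- softmax_vec(yhat)
    p[y] <- p[y] - 1
    p
  }
}

#' Composite objective breakdown
#'
#' `total = L_e + alpha * L_manifold + L_mask`, with every component
#' retained for logging and the manifold monitor.
#'
#' @param l_e Prediction loss.
#' @param l_manifold Manifold smoothness (batch mean).
#' @param l_mask Mask penalty.
#' @param alpha Manifold weight.
#' @return List of class `loss_breakdown` with fields `l_e`, `l_manifold`,
#'   `l_mask`, `alpha`, `total`.
#' @export
total_loss <- function(l_e, l_manifold, l_mask, alpha) {
  structure(list(l_e = l_e, l_manifold = l_manifold, l_mask = l_mask,
                 alpha = alpha,
                 total = l_e + alpha * l_manifold + l_mask),
            class = "loss_breakdown")
}
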