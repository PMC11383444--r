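#' Symmetric edge mask from free parameters
#'
#' `M = sigmoid(V + V^T)`: symmetric by construction, entries strictly in
#' (0, 1). V is the free, trainable matrix.
#'
#' @param v Q x Q numeric matrix of free parameters.
#' @return Q x Q symmetric matrix with entries in (0, 1).
#' @export
mask_from_params <- function(v) {
  v <- as.matrix(v)
  if (any(!is.finite(v))) stop("mask_from_params: non-finite entries in V")
  if (nrow(v) != ncol(v)) stop("mask_from_params: V must be square")
  sigmoid(v + t(v))
}

#' One masked graph-convolution layer
#'
#' `H' = phi((M + I) o S %*% H %*% Theta)` where
#' `S = D^-1/2 (A + I) D^-1/2` is the symmetrically normalized augmented
#' adjacency and `o` the Hadamard product. The added identity guarantees an
#' identity mapping when M = 0 (the filter never degenerates to the null
#' matrix); because the mask enters through a Hadamard product with S, it
#' only modulates existing edges and self-loops.
#'
#' @param h Q x d_in input node features.
#' @param a Q x Q adjacency (zero diagonal; self-loops added internally).
#' @param m Q x Q mask from [mask_from_params()].
#' @param theta d_in x d_out weight matrix.
#' @param phi Activation function (default [relu]; use `identity` for a
#'   linear layer).
#' @return Q x d_out output features.
#' @export
masked_gcn_layer <- function(h, a, m, theta, phi = relu) {
  h <- as.matrix(h); a <- as.matrix(a); m <- as.matrix(m)
  q <- nrow(a)
  if (nrow(h) != q || nrow(m) != q || ncol(m) != q)
    stop("masked_gcn_layer: dimension mismatch between H, A and M")
  if (ncol(h) != nrow(theta))
    stop("masked_gcn_layer: Theta rows must match feature dimension")
  f <- (m + diag(q)) * norm_filter_base(a)
  phi(f %*% h %*% theta)
}

# Glorot-uniform init, deterministic under the caller's RNG state.
glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize the model state
#'
#' Parameters: the shared mask parameters `V` (started at zero, i.e. a
#' uniform mask of 0.5), two graph-layer weight matrices, and a dense
#' readout (one hidden layer, linear output). A single `V` is shared by
#' both graph layers.
#'
#' @param q Number of ROIs.
#' @param d0 Node input dimension.
#' @param dc Anatomical-feature dimension fused after layer 1 (may be 0).
#' @param d1,d2 Graph-layer widths.
#' @param d_hidden Readout hidden width.
#' @param n_out Output dimension (number of regression targets, or number
#'   of classes).
#' @param task `"regression"` or `"classification"`.
#' @param pooling `"mean"` (default), `"sum"` or `"max"`.
#' @return Object of class `maskgnn_state`.
#' @export
init_model_state <- function(q, d0, dc = 0, d1 = 64, d2 = 64,
                             d_hidden = 32, n_out = 1,
                             task = c("regression", "classification"),
                             pooling = c("mean", "sum", "max")) {
  task <- match.arg(task)
  pooling <- match.arg(pooling)
  structure(list(
    V = matrix(0, q, q),
    Theta1 = glorot(d0, d1),
    Theta2 = glorot(d1 + dc, d2),
    W1 = glorot(d2, d_hidden),
    b1 = rep(0, d_hidden),
    W2 = glorot(d_hidden, n_out),
    b2 = rep(0, n_out),
    dims = list(q = q, d0 = d0, dc = dc, d1 = d1, d2 = d2,
                d_hidden = d_hidden, n_out = n_out),
    task = task, pooling = pooling
  ), class = "maskgnn_state")
}

#' Forward pass of the masked GNN
#'
#' Layer 1 on the connectivity-profile features, node-wise concatenation of
#' the anatomical block C, layer 2 (same mask), graph pooling, dense
#' readout. Returns the prediction and, optionally, the cached
#' intermediates needed for backpropagation and attribution.
#'
#' @param graph A `brain_graph` from [build_graph()].
#' @param state A `maskgnn_state`.
#' @param keep_cache Return intermediates (for training/attribution).
#' @return Numeric vector `yhat` of length `n_out`, or a list with `yhat`
#'   and the cache when `keep_cache = TRUE`.
#' @export
model_forward <- function(graph, state, keep_cache = FALSE) {
  d <- state$dims
  q <- d$q
  if (nrow(graph$A) != q) stop("model_forward: graph Q mismatch")
  cmat <- graph$C
  if (ncol(cmat) != d$dc)
    stop("model_forward: anatomical feature dimension mismatch")
  if (d$dc > 0 && (min(cmat) < -1e-9 || max(cmat) > 1 + 1e-9))
    warning("model_forward: anatomical table entries outside [0,1]; expected scaled input")
  m <- mask_from_params(state$V)
  f <- (m + diag(q)) * graph$S
  x1 <- f %*% graph$H0
  pre1 <- x1 %*% state$Theta1
  h1hat <- relu(pre1)
  h1 <- cbind(h1hat, cmat)
  x2 <- f %*% h1
  pre2 <- x2 %*% state$Theta2
  h2 <- relu(pre2)
  p <- switch(state$pooling,
              mean = colMeans(h2),
              sum  = colSums(h2),
              max  = apply(h2, 2, max))
  zpre <- drop(p %*% state$W1) + state$b1
  z <- relu(zpre)
  yhat <- drop(z %*% state$W2) + state$b2
  if (!keep_cache) return(yhat)
  list(yhat = yhat, M = m, F = f, X1 = x1, pre1 = pre1, H1 = h1,
       X2 = x2, pre2 = pre2, H2 = h2, p = p, zpre = zpre, z = z,
       graph = graph)
}

# Backward pass from a gradient d_yhat on the outputs. Returns gradients
# for every parameter plus dC (gradient w.r.t. the fused anatomical block,
# used by Grad-RAM/Grad-CAM). `lap` (unnormalized Laplacian of the binary
# adjacency) and `alpha` add the manifold-smoothness term's gradient
# alpha * 2 L H2 at the last layer.
model_backward <- function(cache, state, d_yhat, alpha = 0, lap = NULL) {
  d <- state$dims
  q <- d$q
  dW2 <- outer(cache$z, d_yhat)
  db2 <- d_yhat
  dz <- drop(state$W2 %*% d_yhat)
  dzpre <- dz * (cache$zpre > 0)
  dW1 <- outer(cache$p, dzpre)
  db1 <- dzpre
  dp <- drop(state$W1 %*% dzpre)
  dH2 <- switch(state$pooling,
    mean = matrix(dp / q, q, d$d2, byrow = TRUE),
    sum  = matrix(dp, q, d$d2, byrow = TRUE),
    max  = {
      g <- matrix(0, q, d$d2)
      idx <- apply(cache$H2, 2, which.max)
      g[cbind(idx, seq_len(d$d2))] <- dp
      g
    })
  if (alpha > 0 && !is.null(lap)) {
    dH2 <- dH2 + alpha * 2 * (lap %*% cache$H2)
  }
  dpre2 <- dH2 * (cache$pre2 > 0)
  dTheta2 <- crossprod(cache$X2, dpre2)
  dX2 <- tcrossprod(dpre2, state$Theta2)
  dF <- tcrossprod(dX2, cache$H1)
  dH1 <- crossprod(cache$F, dX2)
  dC <- if (d$dc > 0) dH1[, d$d1 + seq_len(d$dc), drop = FALSE] else NULL
  dH1hat <- dH1[, seq_len(d$d1), drop = FALSE]
  dpre1 <- dH1hat * (cache$pre1 > 0)
  dTheta1 <- crossprod(cache$X1, dpre1)
  dX1 <- tcrossprod(dpre1, state$Theta1)
  dF <- dF + tcrossprod(dX1, cache$graph$H0)
  dM <- dF * cache$graph$S
  dZ <- dM * cache$M * (1 - cache$M)
  dV <- dZ + t(dZ)
  list(V = dV, Theta1 = dTheta1, Theta2 = dTheta2,
       W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, dC = dC)
}
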