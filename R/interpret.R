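#' Threshold the learned edge mask for visualization
#'
#' Retains off-diagonal mask entries strictly above the visualization
#' threshold `t` (default comparison directly on the (0, 1) mask scale;
#' `double_sigmoid = TRUE` instead compares `sigmoid(M_ij) > t`, in which
#' case meaningful thresholds lie in (0.5, 0.731)). Retained entries keep
#' their mask value; everything else is zero. The diagonal is excluded from
#' reporting.
#'
#' @param m Q x Q mask from [mask_from_params()] (entries in (0, 1)).
#' @param t Visualization threshold in (0, 1).
#' @param double_sigmoid Apply a second sigmoid before comparing.
#' @return Object of class `thresholded_mask`: `values` (Q x Q sparse
#'   pattern), `threshold`, `n_edges`, and `edges` (data.frame sorted by
#'   weight descending, ties broken by (i, j) lexicographic order).
#' @export
threshold_mask <- function(m, t, double_sigmoid = FALSE) {
  m <- as.matrix(m)
  check_square_symmetric(m, "mask")
  if (t <= 0 || t >= 1) stop("threshold_mask: threshold must lie in (0, 1)")
  crit <- if (double_sigmoid) sigmoid(m) else m
  keep <- crit > t
  diag(keep) <- FALSE
  mt <- matrix(0, nrow(m), ncol(m))
  mt[keep] <- m[keep]
  ut <- which(keep & upper.tri(keep), arr.ind = TRUE)
  edges <- data.frame(i = ut[, 1], j = ut[, 2],
                      weight = m[ut])
  if (nrow(edges) > 0)
    edges <- edges[order(-edges$weight, edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(values = mt, threshold = t, n_edges = nrow(edges),
                 edges = edges),
            class = "thresholded_mask")
}

#' @export
#' @method print thresholded_mask
print.thresholded_mask <- function(x, ...) {
  cat(sprintf("<thresholded_mask> t = %g, %d retained edges (Q = %d)\n",
              x$threshold, x$n_edges, nrow(x$values)))
  invisible(x)
}

#' Gradient-based attribution of the anatomical features
#'
#' Grad-RAM (regression) / Grad-CAM (classification) over the fused
#' anatomical block C: per subject, the gradient G of the selected scalar
#' output with respect to C is computed by backpropagation, the activation
#' map is `a = (1/Q) sum_q ReLU(G_q * C_q)` (elementwise product, ReLU
#' keeping only positively contributing features), and a softmax normalizes
#' `a` over the feature columns. The cohort-level score is the mean of the
#' per-subject softmax vectors. In classification mode the gradient is
#' taken on the selected class logit and scores are reported per group
#' (subjects grouped by true label).
#'
#' @param fit A fitted `maskgnn` object (trained with AS among the
#'   modalities).
#' @param cohort Cohort providing the subjects to attribute over.
#' @param ids Subject ids (default: the fit's test split).
#' @param target For regression, the index of the output to attribute
#'   (default 1). Ignored for classification (each group uses its own
#'   class logit).
#' @return For regression: named numeric vector summing to 1 over the d_c
#'   feature columns. For classification: list of per-group vectors.
#' @export
grad_attribution <- function(fit, cohort, ids = NULL, target = 1) {
  stopifnot(inherits(fit, "maskgnn"))
  if (fit$state$dims$dc == 0)
    stop("grad_attribution: model was fitted without anatomical features")
  data <- prepare_graphs(cohort, fit$config)
  if (is.null(ids)) ids <- fit$splits$test
  idx <- match(ids, data$ids)
  if (anyNA(idx)) stop("grad_attribution: unknown subject ids")
  n_out <- fit$state$dims$n_out
  if (fit$config$task == "regression" && (target < 1 || target > n_out))
    stop("grad_attribution: target selector out of range")

  attrib_one <- function(s, sel) {
    fw <- model_forward(data$graphs[[s]], fit$state, keep_cache = TRUE)
    dy <- rep(0, n_out); dy[sel] <- 1
    g <- model_backward(fw, fit$state, dy)$dC
    cmat <- data$graphs[[s]]$C
    a_pre <- colMeans(relu(g * cmat))
    softmax_vec(a_pre)
  }
  feat_names <- colnames(data$graphs[[idx[1]]]$C)
  if (fit$config$task == "regression") {
    a <- rowMeans(vapply(idx, attrib_one, numeric(fit$state$dims$dc),
                         sel = target))
    stats::setNames(a, feat_names)
  } else {
    labels <- data$y[idx, 1]
    out <- lapply(sort(unique(labels)), function(gr) {
      sub <- idx[labels == gr]
      a <- rowMeans(vapply(sub, attrib_one, numeric(fit$state$dims$dc),
                           sel = gr))
      stats::setNames(a, feat_names)
    })
    names(out) <- paste0("group", sort(unique(labels)))
    out
  }
}

#' Network-by-network aggregation of a thresholded mask
#'
#' Aggregates retained mask edges over a functional-network labelling of
#' the ROIs: entry (m, n) is the mean retained mask weight over ROI pairs
#' with labels (m, n), and the density matrix reports retained / possible
#' edge counts per network pair. Unlabelled ROIs (NA) fall into "Others".
#'
#' @param tm A `thresholded_mask`.
#' @param labels Length-Q character vector of network labels (NA allowed).
#' @return List of class `network_aggregate`: `mean_weight` and `density`
#'   (symmetric network x network matrices) and `networks`.
#' @export
network_aggregate <- function(tm, labels) {
  stopifnot(inherits(tm, "thresholded_mask"))
  q <- nrow(tm$values)
  if (length(labels) != q)
    stop("network_aggregate: label vector length must equal Q")
  labels <- as.character(labels)
  labels[is.na(labels)] <- "Others"
  nets <- unique(labels)
  nn <- length(nets)
  wsum <- cnt <- poss <- matrix(0, nn, nn, dimnames = list(nets, nets))
  li <- match(labels, nets)
  for (i in seq_len(q - 1)) {
    for (j in (i + 1):q) {
      a <- li[i]; b <- li[j]
      poss[a, b] <- poss[a, b] + 1
      if (a != b) poss[b, a] <- poss[b, a] + 1
      w <- tm$values[i, j]
      if (w > 0) {
        wsum[a, b] <- wsum[a, b] + w
        cnt[a, b] <- cnt[a, b] + 1
        if (a != b) {
          wsum[b, a] <- wsum[b, a] + w
          cnt[b, a] <- cnt[b, a] + 1
        }
      }
    }
  }
  mean_w <- ifelse(cnt > 0, wsum / pmax(cnt, 1), 0)
  dens <- ifelse(poss > 0, cnt / pmax(poss, 1), 0)
  structure(list(mean_weight = mean_w, density = dens, networks = nets),
            class = "network_aggregate")
}

#' Planted-edge ranking AUC of a learned mask
#'
#' Ranks all off-diagonal ROI pairs by their mask value and measures how
#' well a reference edge set (e.g. the planted edges of a synthetic
#' cohort) is ranked above the rest.
#'
#' @param m Q x Q mask.
#' @param edges Two-column matrix of (i, j) index pairs.
#' @return Ranking AUC in [0, 1].
#' @export
mask_edge_auc <- function(m, edges) {
  m <- as.matrix(m)
  q <- nrow(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  scores <- m[ut]
  key <- pmin(edges[, 1], edges[, 2]) + q * pmax(edges[, 1], edges[, 2])
  pos <- (pmin(ut[, 1], ut[, 2]) + q * pmax(ut[, 1], ut[, 2])) %in% key
  ranking_auc(scores, pos)
}
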