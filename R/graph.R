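#' Sparse adjacency by thresholding and per-node top-k selection
#'
#' Keeps, for every node, its k strongest connections among those exceeding
#' the threshold, then symmetrizes. With the default union rule an edge
#' survives if either endpoint selected it, so node degree may exceed k;
#' nodes with fewer than k supra-threshold connections simply keep what
#' exists. Edge weights carry the input connectivity values (binary
#' adjacency available via `binary = TRUE`). The diagonal is always zero;
#' self-loops are reintroduced inside the model.
#'
#' @param conn Q x Q symmetric nonnegative matrix or `connectivity` object.
#' @param k Number of neighbours retained per node (>= 1).
#' @param threshold Minimum connection weight (default 0.001).
#' @param rule `"union"` (default) or `"intersection"` symmetrization.
#' @param binary Store 1 instead of the weight for kept edges.
#' @return Q x Q symmetric adjacency matrix with zero diagonal.
#' @export
build_adjacency <- function(conn, k = 30, threshold = 0.001,
                            rule = c("union", "intersection"),
                            binary = FALSE) {
  rule <- match.arg(rule)
  m <- if (inherits(conn, "connectivity")) conn$values else as.matrix(conn)
  check_square_symmetric(m, "connectivity")
  if (k < 1) stop("build_adjacency: k must be >= 1")
  if (threshold < 0) stop("build_adjacency: threshold must be >= 0")
  q <- nrow(m)
  w <- m
  diag(w) <- 0
  keep <- matrix(FALSE, q, q)
  for (i in seq_len(q)) {
    cand <- which(w[i, ] > threshold)
    if (length(cand) == 0) next
    top <- cand[order(w[i, cand], decreasing = TRUE)][seq_len(min(k, length(cand)))]
    keep[i, top] <- TRUE
  }
  keep <- if (rule == "union") keep | t(keep) else keep & t(keep)
  a <- matrix(0, q, q)
  a[keep] <- if (binary) 1 else w[keep]
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

#' Node input features from connectivity profiles
#'
#' Each node's feature vector is the concatenation of its FC row and its
#' normalized-SC row, restricted to the active modalities (so d0 = 2Q for
#' FC+SC, Q for a single modality).
#'
#' @param fc,sc Q x Q matrices or `connectivity` objects (either may be NULL
#'   if its modality is inactive).
#' @param modalities Character subset of `c("FC", "SC")`.
#' @return Q x d0 node-feature matrix.
#' @export
build_node_features <- function(fc = NULL, sc = NULL,
                                modalities = c("FC", "SC")) {
  modalities <- intersect(modalities, c("FC", "SC"))
  if (length(modalities) == 0)
    stop("build_node_features: at least one of FC, SC must be active")
  blocks <- list()
  if ("FC" %in% modalities) {
    if (is.null(fc)) stop("build_node_features: FC requested but missing")
    blocks$FC <- if (inherits(fc, "connectivity")) fc$values else as.matrix(fc)
  }
  if ("SC" %in% modalities) {
    if (is.null(sc)) stop("build_node_features: SC requested but missing")
    blocks$SC <- if (inherits(sc, "connectivity")) sc$values else as.matrix(sc)
  }
  qs <- vapply(blocks, nrow, integer(1))
  if (length(unique(qs)) != 1)
    stop("build_node_features: FC and SC must share dimension")
  do.call(cbind, unname(blocks))
}

# Symmetrically normalized augmented adjacency S = D^-1/2 (A + I) D^-1/2.
# Degrees are >= 1 because of the added self-loops, so no zero division.
norm_filter_base <- function(a) {
  at <- a + diag(nrow(a))
  d <- rowSums(at)
  dh <- 1 / sqrt(d)
  at * outer(dh, dh)
}

#' Assemble the per-subject graph consumed by the model
#'
#' @param fc,sc Connectivity matrices (scaled FC, normalized SC).
#' @param as_table Scaled Q x d_c anatomical table or NULL.
#' @param k,threshold Sparsification parameters, see [build_adjacency()].
#' @param modalities Active modalities among `c("FC", "SC", "AS")`.
#' @param graph_from `"FC"` or `"SC"`: which matrix defines the edges
#'   (FC for multimodal runs, SC for SC-only runs).
#' @return A `brain_graph` list: adjacency `A`, normalized filter base `S`,
#'   node features `H0`, anatomical block `C` (possibly 0-column).
#' @export
build_graph <- function(fc = NULL, sc = NULL, as_table = NULL,
                        k = 30, threshold = 0.001,
                        modalities = c("FC", "SC", "AS"),
                        graph_from = NULL) {
  conn_mods <- intersect(modalities, c("FC", "SC"))
  if (is.null(graph_from))
    graph_from <- if ("FC" %in% conn_mods) "FC" else "SC"
  src <- if (graph_from == "FC") fc else sc
  if (is.null(src)) stop("build_graph: graph-defining modality is missing")
  a <- build_adjacency(src, k = k, threshold = threshold)
  h0 <- build_node_features(fc = fc, sc = sc, modalities = conn_mods)
  q <- nrow(a)
  cmat <- if ("AS" %in% modalities && !is.null(as_table)) {
    as.matrix(as_table)
  } else {
    matrix(0, q, 0)
  }
  if (nrow(cmat) != q && ncol(cmat) > 0)
    stop("build_graph: anatomical table row count must equal Q")
  structure(list(A = a, S = norm_filter_base(a), H0 = h0, C = cmat),
            class = "brain_graph")
}
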