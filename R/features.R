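#' Functional connectivity from an ROI time-series matrix
#'
#' Computes the Q x Q matrix of Pearson correlations between every pair of
#' ROI time series. The diagonal is exactly 1 and the result is symmetric.
#'
#' @param ts Numeric T x Q matrix (rows = time points, columns = ROIs), or a
#'   `roi_timeseries` object as returned by [roi_timeseries()].
#' @return A `connectivity` object: Q x Q symmetric matrix with unit
#'   diagonal, modality `"FC"`.
#' @export
compute_fc <- function(ts) {
  x <- as_ts_matrix(ts)
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    stop(sprintf("compute_fc: zero-variance ROI column(s): %s",
                 paste(which(v == 0), collapse = ", ")))
  }
  fc <- stats::cor(x)
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  connectivity(fc, modality = "FC")
}

#' Intrinsic neural timescale per ROI
#'
#' Estimates, for each ROI, the area under the initial positive phase of the
#' sample autocorrelation function, scaled by the repetition time:
#' `INT_q = TR * sum_{k=1}^{N_q} r_q(k)`, where `r_q(k)` is the lag-k
#' autocorrelation computed with a single shared mean and the full
#' sum-of-squares denominator, and `N_q` is the last lag before the first
#' negative autocorrelation. If `r_q(1) < 0` the timescale is 0; if the
#' autocorrelation never turns negative, lags up to `T - 2` are summed.
#'
#' @param ts T x Q numeric matrix or `roi_timeseries` object.
#' @param tr Repetition time in seconds (ignored when `ts` carries its own).
#' @return Length-Q nonnegative vector of timescales in seconds.
#' @export
compute_int <- function(ts, tr = NULL) {
  if (inherits(ts, "roi_timeseries") && is.null(tr)) tr <- ts$tr
  x <- as_ts_matrix(ts)
  if (is.null(tr)) stop("compute_int: repetition time `tr` is required")
  if (tr <= 0) stop("compute_int: tr must be positive")
  n <- nrow(x)
  if (n < 3) stop("compute_int: need at least 3 time points")
  kmax <- n - 2L
  out <- vapply(seq_len(ncol(x)), function(q) {
    y <- x[, q]
    yc <- y - mean(y)
    denom <- sum(yc^2)
    if (denom == 0) stop(sprintf("compute_int: constant signal in ROI %d", q))
    # walk the autocorrelation sequence, stopping at the first sign change
    acc <- 0
    for (k in seq_len(kmax)) {
      rk <- sum(yc[(k + 1):n] * yc[1:(n - k)]) / denom
      if (rk < 0) break
      acc <- acc + rk
    }
    tr * acc
  }, numeric(1))
  pmax(out, 0)
}

#' Volume-normalized structural connectivity
#'
#' Divides each raw streamline count by the square root of the product of
#' the gray-matter volumes of the two connected regions, then min-max scales
#' the off-diagonal entries to [0, 1]. The diagonal stays zero.
#'
#' @param raw Q x Q symmetric nonnegative raw count matrix (or `connectivity`
#'   object of modality `"SC"`).
#' @param gm_volumes Length-Q vector of strictly positive gray-matter
#'   volumes.
#' @return A `connectivity` object, modality `"SC"`, `normalized = TRUE`.
#' @export
normalize_sc <- function(raw, gm_volumes) {
  m <- if (inherits(raw, "connectivity")) raw$values else raw
  check_square_symmetric(m, "raw SC")
  if (any(m < 0)) stop("normalize_sc: raw SC entries must be nonnegative")
  q <- nrow(m)
  if (length(gm_volumes) != q)
    stop("normalize_sc: gm_volumes length must equal matrix dimension")
  if (any(gm_volumes <= 0))
    stop("normalize_sc: gray-matter volumes must be strictly positive")
  denom <- sqrt(outer(gm_volumes, gm_volumes))
  out <- m / denom
  diag(out) <- 0
  off <- upper.tri(out) | lower.tri(out)
  vals <- out[off]
  rng <- range(vals)
  out[off] <- if (rng[1] == rng[2]) 0 else (vals - rng[1]) / (rng[2] - rng[1])
  out <- (out + t(out)) / 2
  connectivity(out, modality = "SC", normalized = TRUE)
}

#' Log + min-max scaling of an anatomical-statistics table
#'
#' Per column: a logarithmic transform to stabilize variance, then min-max
#' scaling to [0, 1]. By default `log1p` is used after shifting each column
#' so its minimum argument is nonnegative, which tolerates the zeros and the
#' bounded negative values (structure-function coupling) that ROI feature
#' columns can contain. Strictly positive columns may use a plain log.
#'
#' @param tab Q x d numeric matrix or data.frame of ROI features.
#' @param log_fn `"log1p"` (default, shift-safe) or `"log"` (requires
#'   strictly positive columns).
#' @return Matrix of the same shape with all entries in [0, 1]; constant
#'   columns map to zeros.
#' @export
scale_anatomical <- function(tab, log_fn = c("log1p", "log")) {
  log_fn <- match.arg(log_fn)
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("scale_anatomical: non-finite values in table")
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    if (log_fn == "log") {
      if (any(x <= 0))
        stop(sprintf("scale_anatomical: column %d not strictly positive for plain log", j))
      x <- log(x)
    } else {
      shift <- max(0, -min(x))
      x <- log1p(x + shift)
    }
    m[, j] <- minmax_scale(x)
  }
  m
}

#' Structure-function coupling per ROI
#'
#' For each region, the Spearman rank correlation between its structural
#' connectivity profile (row of SC) and its functional connectivity profile
#' (row of FC), restricted to the other regions it is structurally connected
#' to (SC > 0), excluding the diagonal. Regions with fewer than 3 nonzero
#' structural connections get a coupling of 0 and are flagged.
#'
#' @param sc Q x Q normalized SC matrix (or `connectivity` object).
#' @param fc Q x Q FC matrix (or `connectivity` object).
#' @return Length-Q vector in [-1, 1] with attribute `"imputed"` marking
#'   regions whose coupling was undefined and set to 0.
#' @export
compute_coupling <- function(sc, fc) {
  s <- if (inherits(sc, "connectivity")) sc$values else sc
  f <- if (inherits(fc, "connectivity")) fc$values else fc
  check_square_symmetric(s, "SC")
  check_square_symmetric(f, "FC")
  q <- nrow(s)
  if (nrow(f) != q) stop("compute_coupling: SC and FC must share dimension")
  if (all(s == 0)) stop("compute_coupling: all-zero SC matrix")
  imputed <- logical(q)
  rho <- vapply(seq_len(q), function(i) {
    idx <- setdiff(which(s[i, ] > 0), i)
    if (length(idx) < 3) {
      imputed[i] <<- TRUE
      return(0)
    }
    r <- suppressWarnings(
      stats::cor(s[i, idx], f[i, idx], method = "spearman"))
    if (!is.finite(r)) {
      imputed[i] <<- TRUE
      return(0)
    }
    r
  }, numeric(1))
  attr(rho, "imputed") <- imputed
  rho
}

#' Assemble the full per-ROI feature table
#'
#' Binds the morphology columns, the intrinsic neural timescale and the
#' structure-function coupling into one table (default 9 + 1 + 1 = 11
#' columns, in that fixed order) and applies [scale_anatomical()].
#'
#' @param morphology Q x m matrix of morphology columns (m may be 0 for
#'   ablations); column names are preserved.
#' @param int_vec Length-Q intrinsic-timescale vector.
#' @param coupling_vec Length-Q coupling vector.
#' @param scale Apply log + min-max scaling (default TRUE).
#' @return Q x (m + 2) matrix with named columns (`INT`, `Coupling` last).
#' @export
assemble_as <- function(morphology, int_vec, coupling_vec, scale = TRUE) {
  m <- as.matrix(morphology)
  if (ncol(m) > 0 && nrow(m) != length(int_vec))
    stop("assemble_as: morphology row count must equal length of int_vec")
  if (length(int_vec) != length(coupling_vec))
    stop("assemble_as: INT and coupling vectors must share length")
  if (ncol(m) > 0 && is.null(colnames(m)))
    colnames(m) <- paste0("morph", seq_len(ncol(m)))
  out <- cbind(m, INT = int_vec, Coupling = coupling_vec)
  if (scale) {
    nm <- colnames(out)
    out <- scale_anatomical(out)
    colnames(out) <- nm
  }
  out
}

#' The nine standard surface-morphology column names
#' @return Character vector of length 9.
#' @export
morphology_columns <- function() {
  c("NumVertices", "SurfaceArea", "GrayMatterVolume",
    "ThicknessMean", "ThicknessStd", "MeanCurvature",
    "GaussianCurvature", "IntrinsicCurvatureIndex", "FoldingIndex")
}
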