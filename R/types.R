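#' ROI time-series container
#'
#' @param values T x Q numeric matrix, rows = time points, columns = ROIs.
#' @param tr Repetition time in seconds.
#' @param roi_ids Optional length-Q labels (defaults to `ROI1..ROIQ`).
#' @return Object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, tr, roi_ids = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 3) stop("roi_timeseries: need at least 3 time points")
  if (any(!is.finite(values))) stop("roi_timeseries: non-finite entries")
  if (!is.numeric(tr) || length(tr) != 1 || tr <= 0)
    stop("roi_timeseries: tr must be a positive scalar (seconds)")
  if (is.null(roi_ids)) roi_ids <- paste0("ROI", seq_len(ncol(values)))
  if (length(roi_ids) != ncol(values))
    stop("roi_timeseries: roi_ids length must match column count")
  structure(list(values = values, tr = tr, roi_ids = roi_ids),
            class = "roi_timeseries")
}

as_ts_matrix <- function(ts) {
  x <- if (inherits(ts, "roi_timeseries")) ts$values else as.matrix(ts)
  if (any(!is.finite(x))) stop("time-series matrix has non-finite entries")
  x
}

#' Connectivity-matrix container
#'
#' Wraps a symmetric nonnegative (SC) or correlation (FC) matrix with its
#' modality tag and normalization flag, enforcing the modality invariants:
#' FC has unit diagonal (pre-scaling) and entries in [-1, 1]; SC is
#' nonnegative with zero diagonal.
#'
#' @param values Q x Q numeric matrix.
#' @param modality `"FC"` or `"SC"`.
#' @param normalized Whether min-max (and, for SC, volume) normalization has
#'   been applied.
#' @param roi_ids Optional ROI labels.
#' @return Object of class `connectivity`.
#' @export
connectivity <- function(values, modality = c("FC", "SC"),
                         normalized = FALSE, roi_ids = NULL) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  check_square_symmetric(values, sprintf("%s matrix", modality))
  if (modality == "FC" && !normalized) {
    if (max(abs(diag(values) - 1)) > 1e-8)
      stop("connectivity: FC diagonal must be 1 before scaling")
    if (min(values) < -1 - 1e-8 || max(values) > 1 + 1e-8)
      stop("connectivity: FC entries must lie in [-1, 1]")
  }
  if (modality == "SC") {
    if (any(values < 0)) stop("connectivity: SC entries must be nonnegative")
    if (any(diag(values) != 0)) stop("connectivity: SC diagonal must be zero")
  }
  if (is.null(roi_ids)) roi_ids <- paste0("ROI", seq_len(ncol(values)))
  structure(list(values = values, modality = modality,
                 normalized = normalized, roi_ids = roi_ids),
            class = "connectivity")
}

#' @export
#' @method print connectivity
print.connectivity <- function(x, ...) {
  cat(sprintf("<connectivity> %s, Q = %d, normalized = %s\n",
              x$modality, nrow(x$values), x$normalized))
  invisible(x)
}

#' @export
#' @method print roi_timeseries
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> T = %d, Q = %d, TR = %g s\n",
              nrow(x$values), ncol(x$values), x$tr))
  invisible(x)
}
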