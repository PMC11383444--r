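#' Min-max scaling to [0, 1]
#'
#' Rescales a numeric vector or matrix linearly so its minimum maps to 0 and
#' its maximum to 1. A constant input (zero range) maps to all zeros, which
#' keeps degenerate inputs inside the target range without a 0/0.
#'
#' @param x Numeric vector or matrix with finite entries.
#' @return Object of the same shape with entries in [0, 1].
#' @export
#' @examples
#' minmax_scale(c(2, 4, 6))
minmax_scale <- function(x) {
  if (!is.numeric(x)) stop("minmax_scale: input must be numeric")
  if (any(!is.finite(x))) stop("minmax_scale: non-finite entries in input")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    x[] <- 0
    return(x)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' @keywords internal
check_square_symmetric <- function(m, name = "matrix", tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(sprintf("%s must be a square matrix", name))
  if (max(abs(m - t(m))) > tol)
    stop(sprintf("%s must be symmetric (tolerance %g)", name, tol))
  invisible(TRUE)
}

# Deterministic child seed for a named stage, derived from a master seed.
# Keeps every stage below .Machine$integer.max.
derive_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage)) %% 10000L
  (as.integer(seed) %% 2000000L) * 1000L + offs
}
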