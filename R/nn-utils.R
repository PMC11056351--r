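#' @keywords internal
#' @useDynLib scmix, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

## Numerical primitives shared by all layers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exact Gaussian error linear unit
#'
#' The erf-based GELU, `x * pnorm(x)`, used after every convolution and inside
#' the transformer MLPs.
#'
#' @param x numeric vector/array.
#' @return array of the same shape.
#' @export
gelu <- function(x) x * stats::pnorm(x)

## dGELU/dx = Phi(x) + x phi(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

#' Row-wise numerically stable softmax
#'
#' Subtracts the row maximum before exponentiating.
#'
#' @param z numeric matrix (rows are independent distributions over columns).
#' @return matrix whose rows are nonnegative and sum to 1.
#' @export
softmax_rows <- function(z) {
  z <- as.matrix(z)
  rmax <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - rmax)
  e / rowSums(e)
}

## truncated-normal initializer (resample outside +-2 sd)
init_trunc_normal <- function(n, std = 0.02) {
  x <- stats::rnorm(n, 0, std)
  bad <- abs(x) > 2 * std
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, std)
    bad <- abs(x) > 2 * std
  }
  x
}

## add a row vector to every row of a matrix
add_rowvec <- function(m, v) add_rowvec_cpp(m, v)

## feature maps are (N, H, W, C); token grids (N, gh, gw, D); tokens (N, T, D)

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(TRUE)
}
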