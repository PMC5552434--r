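#' Squared-exponential (ARD) kernel parameters
#'
#' @param variance Signal variance, sigma_f^2 > 0.
#' @param lengthscales One positive lengthscale per input dimension
#'   (recycled if scalar).
#' @param jitter Small positive value added to the diagonal of
#'   self-covariance matrices for numerical stability.
#' @return An object of class `"kernel_params"`.
#' @export
kernel_params <- function(variance = 1, lengthscales = 1, jitter = 1e-6) {
  if (variance <= 0 || any(lengthscales <= 0) || jitter <= 0)
    stop("kernel parameters must all be positive", call. = FALSE)
  structure(list(variance = variance, lengthscales = as.numeric(lengthscales),
                 jitter = jitter),
            class = "kernel_params")
}

as_input_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(dim(X))) X <- matrix(as.numeric(X), ncol = 1L)
  storage.mode(X) <- "double"
  X
}

#' Squared-exponential covariance between two input sets
#'
#' `K[i, j] = variance * exp(-0.5 * sum_d ((X1[i,d] - X2[j,d]) / l_d)^2)`.
#' When `X1` and `X2` are the same object, `jitter` is added to the
#' diagonal.
#'
#' @param X1,X2 Input matrices (rows = points, columns = dimensions);
#'   vectors are treated as single-column matrices.
#' @param params A [kernel_params()].
#' @return The covariance matrix.
#' @export
se_kernel <- function(X1, X2 = X1, params = kernel_params()) {
  same <- missing(X2) || identical(X1, X2)
  K <- kern_cross(X1, X2, params)
  if (same) K <- K + diag(params$jitter, nrow(K))
  K
}

# cross-covariance, never jittered (used for prediction)
kern_cross <- function(X1, X2, params) {
  stopifnot(inherits(params, "kernel_params"))
  X1 <- as_input_matrix(X1); X2 <- as_input_matrix(X2)
  if (ncol(X1) != ncol(X2))
    stop("input dimensionality mismatch: ", ncol(X1), " vs ", ncol(X2),
         call. = FALSE)
  ell <- rep_len(params$lengthscales, ncol(X1))
  X1s <- sweep(X1, 2L, ell, "/")
  X2s <- sweep(X2, 2L, ell, "/")
  d2 <- outer(rowSums(X1s^2), rowSums(X2s^2), "+") - 2 * tcrossprod(X1s, X2s)
  params$variance * exp(-0.5 * pmax(d2, 0))
}

# d k(x*, x_i) / d x*_dim for the SE kernel: rows = x*, cols = training X.
se_kernel_grad <- function(Xstar, X, params, dim = 1L) {
  Xstar <- as_input_matrix(Xstar); X <- as_input_matrix(X)
  ell <- rep_len(params$lengthscales, ncol(X))
  K <- kern_cross(Xstar, X, params)
  K * outer(Xstar[, dim], X[, dim], function(a, b) (b - a) / ell[dim]^2)
}

# Var of the derivative process at x*: d^2 k / (dx dx') at lag 0.
se_kernel_deriv_var <- function(params, dim = 1L, ndim = 1L) {
  ell <- rep_len(params$lengthscales, ndim)
  params$variance / ell[dim]^2
}
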