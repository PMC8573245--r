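#' Kernel specification
#'
#' A kernel specification names the kernel family used for the kernelized
#' hyperplane solve and, for the radial basis function (RBF) family, its
#' bandwidth. The RBF kernel is \eqn{K(x_i, x_j) = \exp(-\gamma \|x_i -
#' x_j\|^2)} with \eqn{\gamma > 0}; the linear kernel is the plain dot
#' product \eqn{x_i^\top x_j} and ignores `gamma`.
#'
#' `gamma = 0` is rejected rather than treated as the constant-1 limit: a
#' zero-bandwidth Gram matrix is the all-ones matrix, which makes the
#' regularized local solve degenerate in an uninformative way.
#'
#' @param family `"rbf"` or `"linear"`.
#' @param gamma Positive RBF bandwidth (dimensionless). Ignored for
#'   `family = "linear"`.
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec("rbf", gamma = 2^-3)
#' kernel_spec("linear")
#' @export
kernel_spec <- function(family = c("rbf", "linear"), gamma = 1) {
  family <- match.arg(family)
  if (family == "rbf") {
    if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
        gamma <= 0) {
      stop("rbf kernel requires a single finite gamma > 0", call. = FALSE)
    }
  }
  structure(list(family = family, gamma = if (family == "rbf") gamma else NA_real_),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  if (x$family == "rbf") {
    cat(sprintf("<kernel_spec> rbf, gamma = %g\n", x$gamma))
  } else {
    cat("<kernel_spec> linear\n")
  }
  invisible(x)
}

is_kernel_spec <- function(x) inherits(x, "kernel_spec")

#' Evaluate a kernel on a pair of vectors
#'
#' RBF: `exp(-gamma * sum((xi - xj)^2))`, in (0, 1] with value 1 iff the
#' vectors coincide. Linear: `sum(xi * xj)`. The squared distance is formed
#' directly from the difference vector (not via the norm-expansion
#' shortcut), so near-identical inputs cannot produce a small negative
#' squared distance through cancellation.
#'
#' @param xi,xj Numeric vectors of equal length.
#' @param spec A [kernel_spec()].
#' @return A single numeric kernel value.
#' @examples
#' kernel_value(c(0, 0), c(1, 1), kernel_spec("rbf", gamma = 2^-3))
#' kernel_value(c(1, 2), c(3, 4), kernel_spec("linear"))
#' @export
kernel_value <- function(xi, xj, spec) {
  stopifnot(is_kernel_spec(spec))
  xi <- as.numeric(xi)
  xj <- as.numeric(xj)
  if (length(xi) != length(xj) || length(xi) < 1L) {
    stop("kernel_value: xi and xj must be non-empty vectors of equal length",
         call. = FALSE)
  }
  if (spec$family == "rbf") {
    exp(-spec$gamma * sum((xi - xj)^2))
  } else {
    sum(xi * xj)
  }
}

#' Gram matrix of a set of vectors
#'
#' Entry (i, j) is `kernel_value(vectors[i, ], vectors[j, ], spec)`. The
#' result is symmetric; for the RBF family the diagonal is exactly 1 and
#' the matrix is positive semidefinite.
#'
#' @param vectors Numeric matrix, one vector per row (a plain vector is
#'   treated as a single row).
#' @param spec A [kernel_spec()].
#' @return A `nrow(vectors)` square symmetric matrix.
#' @export
gram_matrix <- function(vectors, spec) {
  stopifnot(is_kernel_spec(spec))
  vectors <- as_row_matrix(vectors)
  k <- nrow(vectors)
  G <- matrix(0, k, k)
  for (i in seq_len(k)) {
    G[i, i] <- kernel_value(vectors[i, ], vectors[i, ], spec)
    for (j in seq_len(i - 1L)) {
      G[i, j] <- G[j, i] <- kernel_value(vectors[i, ], vectors[j, ], spec)
    }
  }
  G
}

#' Cross-kernel vector between a set of vectors and one query
#'
#' Entry i is `kernel_value(vectors[i, ], query, spec)`; this is the
#' k-by-1 right-hand side of the kernelized coefficient system.
#'
#' @inheritParams gram_matrix
#' @param query Numeric vector with the same dimension as the rows of
#'   `vectors`.
#' @return Numeric vector of length `nrow(vectors)`.
#' @export
cross_kernel <- function(vectors, query, spec) {
  stopifnot(is_kernel_spec(spec))
  vectors <- as_row_matrix(vectors)
  query <- as.numeric(query)
  if (ncol(vectors) != length(query)) {
    stop("cross_kernel: query dimension does not match vectors", call. = FALSE)
  }
  vapply(seq_len(nrow(vectors)),
         function(i) kernel_value(vectors[i, ], query, spec),
         numeric(1))
}

# Coerce a vector or matrix to a one-row-per-vector numeric matrix,
# rejecting ragged / non-numeric input.
as_row_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expected a numeric matrix of row vectors", call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("expected at least one non-empty vector", call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}
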