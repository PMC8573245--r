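#' Nearest same-class neighbors of a query
#'
#' Selects the k training rows of one class nearest to the query in
#' Euclidean input-space distance, and forms the local-hyperplane
#' ingredients: the neighbor centroid \eqn{\bar N^c} and the centered
#' difference vectors \eqn{V_i^c = N_i^c - \bar N^c}. Neighbor selection
#' uses input-space distance for both the linear and the kernel paths.
#'
#' If the class has m < k members, all m are returned and the effective k
#' is recorded (`k_requested` keeps the original). Distance ties are broken
#' toward the smaller training-row index.
#'
#' @param query Numeric vector of length d.
#' @param table A [feature_table()].
#' @param class_id Class id present in `table`.
#' @param k Number of neighbors requested, `k >= 1`.
#' @return An object of class `neighbor_set`: `class_id`, `neighbors`
#'   (k x d), `centroid`, `diffs` (k x d, rows summing to zero), `k`
#'   (effective), `k_requested`, `row_index` (indices into the table).
#' @export
find_class_neighbors <- function(query, table, class_id, k) {
  stopifnot(is_feature_table(table))
  query <- as.numeric(query)
  d <- ncol(table$values)
  if (length(query) != d) stop("query dimension does not match table", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  rows <- which(table$labels == class_id)
  if (length(rows) == 0L) {
    stop(sprintf("class %d has no members in the table", class_id), call. = FALSE)
  }
  member <- table$values[rows, , drop = FALSE]
  d2 <- rowSums(sweep(member, 2L, query)^2)
  ord <- order(d2, rows)                       # ties -> smaller training-row index
  k_eff <- min(as.integer(k), length(rows))
  take <- ord[seq_len(k_eff)]
  nb <- member[take, , drop = FALSE]
  centroid <- colMeans(nb)
  diffs <- sweep(nb, 2L, centroid)
  structure(list(class_id = as.integer(class_id),
                 neighbors = nb,
                 centroid = centroid,
                 diffs = diffs,
                 k = k_eff,
                 k_requested = as.integer(k),
                 row_index = rows[take]),
            class = "neighbor_set")
}

# Solve the symmetric positive (semi)definite system (A + lambda I) a = b
# by Cholesky; one iterative-refinement step if the residual exceeds tol.
spd_solve <- function(A, b, tol = 1e-10) {
  R <- chol(A)
  a <- backsolve(R, backsolve(R, b, transpose = TRUE))
  r <- b - A %*% a
  if (max(abs(r)) > tol * max(1, max(abs(b)))) {
    a <- a + backsolve(R, backsolve(R, r, transpose = TRUE))
  }
  drop(a)
}

#' Linear-path local hyperplane coefficients and decision distance
#'
#' Solves the ridge-regularized least-squares system
#' \deqn{(V^c (V^c)^\top + \lambda I)\,\alpha^c = V^c (x - \bar N^c)}
#' for the coefficients of the query's projection onto the class's local
#' hyperplane (rows of `nbrs$diffs` are the \eqn{V_i^c}). The decision
#' distance is the squared residual \eqn{\|x - \bar N^c - \sum_i \alpha_i
#' V_i^c\|^2} — the quantity the classifier minimizes over classes — and
#' excludes the regularization term, which enters only the fitting
#' objective `objective_value = decision_distance_sq + lambda * ||alpha||^2`.
#'
#' With `lambda_reg = 0` the system can be singular; it is then solved in
#' the minimum-norm sense via the pseudoinverse and flagged with
#' `singular = TRUE`.
#'
#' @param nbrs A `neighbor_set` from [find_class_neighbors()].
#' @param query Numeric vector of length d.
#' @param lambda_reg Ridge parameter, `>= 0` (default 1).
#' @return An object of class `hyperplane_solution`: `alpha`, `lambda_reg`,
#'   `decision_distance_sq`, `objective_value`, `singular`, `class_id`.
#' @export
solve_alpha_linear <- function(nbrs, query, lambda_reg = 1) {
  stopifnot(inherits(nbrs, "neighbor_set"))
  query <- as.numeric(query)
  if (length(query) != ncol(nbrs$diffs)) {
    stop("query dimension does not match neighbor set", call. = FALSE)
  }
  if (lambda_reg < 0) stop("lambda_reg must be nonnegative", call. = FALSE)
  D <- nbrs$diffs                              # k x d, rows V_i^c
  xb <- query - nbrs$centroid                  # x - Nbar_c
  k <- nrow(D)
  A <- D %*% t(D)
  b <- drop(D %*% xb)
  singular <- FALSE
  if (lambda_reg > 0) {
    alpha <- spd_solve(A + diag(lambda_reg, k), b)
  } else {
    alpha <- tryCatch(spd_solve(A, b), error = function(e) NULL)
    if (is.null(alpha)) {
      # minimum-norm solution of the rank-deficient normal system
      sv <- svd(A)
      pos <- sv$d > max(sv$d[1], 1) * 1e-12
      alpha <- drop(sv$v[, pos, drop = FALSE] %*%
                      ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos]))
      singular <- TRUE
    }
  }
  res <- xb - drop(t(D) %*% alpha)
  d2 <- sum(res^2)
  new_hyperplane_solution(alpha, lambda_reg, d2, d2 + lambda_reg * sum(alpha^2),
                          singular, nbrs$class_id)
}

#' Kernel-path local hyperplane coefficients and decision distance
#'
#' The kernelized solve. The centered query \eqn{\bar x = x - \bar N^c}
#' and the difference vectors \eqn{V_i^c} are formed in input space first
#' and only then pushed through the kernel (this is not the same as
#' centering in feature space, and is deliberate):
#' \deqn{\alpha^c = (K(V^c, V^c) + \lambda I)^{-1} K(V^c, \bar x)}
#' with feature-space squared residual
#' \deqn{K(\bar x, \bar x) - 2 \alpha^\top K(V^c, \bar x) +
#'       \alpha^\top K(V^c, V^c) \alpha,}
#' clamped at 0 against floating-point cancellation.
#'
#' @inheritParams solve_alpha_linear
#' @param kernel A [kernel_spec()].
#' @param lambda_reg Ridge parameter, strictly positive here: the kernel
#'   path relies on `Gram + lambda I` being nonsingular.
#' @return An object of class `hyperplane_solution` (see
#'   [solve_alpha_linear()]).
#' @export
solve_alpha_kernel <- function(nbrs, query, kernel, lambda_reg = 1) {
  stopifnot(inherits(nbrs, "neighbor_set"), is_kernel_spec(kernel))
  query <- as.numeric(query)
  if (length(query) != ncol(nbrs$diffs)) {
    stop("query dimension does not match neighbor set", call. = FALSE)
  }
  if (!is.numeric(lambda_reg) || lambda_reg <= 0) {
    stop("the kernel path requires lambda_reg > 0", call. = FALSE)
  }
  D <- nbrs$diffs
  xb <- query - nbrs$centroid
  K <- gram_matrix(D, kernel)
  kx <- cross_kernel(D, xb, kernel)
  kxx <- kernel_value(xb, xb, kernel)
  alpha <- spd_solve(K + diag(lambda_reg, nrow(D)), kx)
  d2 <- kxx - 2 * sum(alpha * kx) + drop(crossprod(alpha, K %*% alpha))
  d2 <- max(d2, 0)
  new_hyperplane_solution(alpha, lambda_reg, d2, d2 + lambda_reg * sum(alpha^2),
                          FALSE, nbrs$class_id)
}

new_hyperplane_solution <- function(alpha, lambda_reg, d2, obj, singular, class_id) {
  structure(list(alpha = alpha,
                 lambda_reg = lambda_reg,
                 decision_distance_sq = d2,
                 objective_value = obj,
                 singular = singular,
                 class_id = class_id),
            class = "hyperplane_solution")
}

#' Classify a query by minimum local-hyperplane distance
#'
#' For each class, the query's k nearest same-class neighbors define a
#' local hyperplane; the query is assigned to the class whose hyperplane
#' is nearest in (regularized) squared distance. `kernel = NULL` selects
#' the linear HKNN path; a [kernel_spec()] selects the kernelized KHKNN
#' path. Exact distance ties go to the smaller class id.
#'
#' @param query Numeric vector of length d.
#' @param table A [feature_table()] with at least two classes.
#' @param k Neighbors per class (capped at the class size).
#' @param kernel `NULL` (linear path) or a [kernel_spec()].
#' @param lambda_reg Ridge parameter (default 1).
#' @return An object of class `distance_profile`: `per_class_distance_sq`
#'   (length C, ordered by class id), `predicted_class`, `solutions`.
#' @examples
#' ft <- generate_blobs(20, dims = 2, separation_sd = 6, seed = 1)
#' classify(c(0, 0), ft, k = 3, kernel = kernel_spec("rbf", 0.125))
#' @export
classify <- function(query, table, k, kernel = NULL, lambda_reg = 1) {
  stopifnot(is_feature_table(table))
  if (table$n_classes < 2L) stop("classification needs at least 2 classes", call. = FALSE)
  query <- as.numeric(query)
  if (length(query) != ncol(table$values)) {
    stop("query dimension does not match table", call. = FALSE)
  }
  classes <- 0:(table$n_classes - 1L)
  sols <- lapply(classes, function(c_id) {
    nb <- find_class_neighbors(query, table, c_id, k)
    if (is.null(kernel)) {
      solve_alpha_linear(nb, query, lambda_reg)
    } else {
      solve_alpha_kernel(nb, query, kernel, lambda_reg)
    }
  })
  d2 <- vapply(sols, function(s) s$decision_distance_sq, numeric(1))
  structure(list(per_class_distance_sq = d2,
                 predicted_class = classes[which.min(d2)],  # first min = smallest id
                 solutions = sols),
            class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat("<distance_profile> predicted class:", x$predicted_class, "\n")
  cat("  squared distances:",
      paste(sprintf("%d: %.6g", seq_along(x$per_class_distance_sq) - 1L,
                    x$per_class_distance_sq), collapse = ", "), "\n")
  invisible(x)
}

#' Classify a batch of queries
#'
#' Elementwise [classify()] over the rows of a query matrix; order is
#' preserved.
#'
#' @param queries Numeric m x d matrix (m may be 0).
#' @inheritParams classify
#' @return List of `distance_profile`, one per query row.
#' @export
classify_batch <- function(queries, table, k, kernel = NULL, lambda_reg = 1) {
  if (is.null(dim(queries))) {
    if (length(queries) == 0L) return(list())
    queries <- matrix(queries, nrow = 1L)
  }
  lapply(seq_len(nrow(queries)), function(i) {
    classify(queries[i, ], table, k, kernel, lambda_reg)
  })
}
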