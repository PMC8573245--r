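# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately avoid the package's solve/classify code paths:
# distances are brute-forced, coefficient solutions come from a
# general-purpose numerical minimizer, kernels are re-evaluated inline.

# Random two-class instance: table + one query, both classes guaranteed.
random_instance <- function(n, d, seed) {
  set.seed(seed)
  labels <- c(0L, 1L, sample(0:1, n - 2L, replace = TRUE))
  values <- matrix(rnorm(n * d), n, d)
  list(table = feature_table(values, labels), query = rnorm(d))
}

# Brute-force per-class nearest-neighbor squared distances (input space).
brute_class_nn_sq <- function(query, table) {
  vapply(0:(table$n_classes - 1L), function(c_id) {
    member <- table$values[table$labels == c_id, , drop = FALSE]
    min(rowSums(sweep(member, 2L, query)^2))
  }, numeric(1))
}

rbf_inline <- function(a, b, gamma) exp(-gamma * sum((a - b)^2))

# Numerical minimizer of the linear-path ridge objective
# ||xb - t(D) alpha||^2 + lambda ||alpha||^2, starting from zero.
optim_alpha_linear <- function(D, xb, lambda) {
  f <- function(a) sum((xb - drop(t(D) %*% a))^2) + lambda * sum(a^2)
  stats::optim(rep(0, nrow(D)), f, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))$par
}

# Numerical minimizer of the kernelized objective, with the kernel
# re-evaluated inline (not via the package's gram_matrix).
optim_alpha_rbf <- function(D, xb, gamma, lambda) {
  k <- nrow(D)
  K <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    K[i, j] <- rbf_inline(D[i, ], D[j, ], gamma)
  }
  kx <- vapply(seq_len(k), function(i) rbf_inline(D[i, ], xb, gamma), numeric(1))
  kxx <- 1  # rbf of a point with itself
  f <- function(a) {
    kxx - 2 * sum(a * kx) + drop(crossprod(a, K %*% a)) + lambda * sum(a^2)
  }
  stats::optim(rep(0, k), f, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))$par
}

# Hand-built 6-point one-dimensional table used by the jackknife tests.
tiny_1d_table <- function() {
  feature_table(matrix(c(-2, -1, -1.5, 2, 1, 1.5), ncol = 1),
                c(0L, 0L, 0L, 1L, 1L, 1L))
}
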