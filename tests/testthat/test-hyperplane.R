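test_that("neighbor selection matches a brute-force distance sort", {
  tab <- feature_table(matrix(c(0, 1, 5, 2, 3, 4), ncol = 1),
                       c(0L, 0L, 0L, 1L, 1L, 1L))
  nb <- find_class_neighbors(0.4, tab, 0L, k = 2)
  expect_equal(sort(drop(nb$neighbors)), c(0, 1))
  expect_equal(unname(nb$centroid), 0.5)
  expect_equal(sort(drop(nb$diffs)), c(-0.5, 0.5))
  # k equal to the class size returns the whole class
  nb_all <- find_class_neighbors(0.4, tab, 0L, k = 3)
  expect_equal(sort(drop(nb_all$neighbors)), c(0, 1, 5))
  expect_equal(unname(nb_all$centroid), 2)
  # k beyond the class size is capped, with the request remembered
  nb_cap <- find_class_neighbors(0.4, tab, 0L, k = 10)
  expect_equal(nb_cap$k, 3L)
  expect_equal(nb_cap$k_requested, 10L)
})

test_that("neighbor set satisfies its centroid/centering invariants", {
  set.seed(31)
  for (i in 1:10) {
    inst <- random_instance(n = 25, d = 5, seed = 100 + i)
    nb <- find_class_neighbors(inst$query, inst$table, 1L, k = 4)
    expect_equal(unname(nb$centroid), unname(colMeans(nb$neighbors)), tolerance = 1e-12)
    expect_equal(unname(colSums(nb$diffs)), rep(0, 5), tolerance = 1e-12)
  }
})

test_that("equidistant neighbors are taken by ascending row index", {
  tab <- feature_table(matrix(c(-1, 1, -1, 5, 6), ncol = 1),
                       c(0L, 0L, 0L, 1L, 1L))
  nb <- find_class_neighbors(0, tab, 0L, k = 1)   # rows 1 and 2 both at distance 1
  expect_equal(nb$row_index, 1L)
})

test_that("linear solve: centroid query, ridge shrinkage, singular flag", {
  set.seed(41)
  inst <- random_instance(n = 30, d = 4, seed = 7)
  nb <- find_class_neighbors(inst$query, inst$table, 0L, k = 3)
  # query at the centroid: zero right-hand side, zero distance
  sol0 <- solve_alpha_linear(nb, nb$centroid, lambda_reg = 1)
  expect_equal(sol0$alpha, rep(0, 3))
  expect_equal(sol0$decision_distance_sq, 0)
  # enormous ridge shrinks the coefficients essentially to zero
  base <- solve_alpha_linear(nb, inst$query, lambda_reg = 1e-8)
  big <- solve_alpha_linear(nb, inst$query, lambda_reg = 1e9)
  expect_lte(sqrt(sum(big$alpha^2)), 1e-6 * sqrt(sum(base$alpha^2)))
  # objective always dominates the penalty term
  expect_gte(base$objective_value, 1e-8 * sum(base$alpha^2) - 1e-10)
  # duplicated neighbors at lambda = 0: minimum-norm solution, flagged
  dup <- feature_table(matrix(c(1, 1, 1, 4, 5), ncol = 1),
                       c(0L, 0L, 0L, 1L, 1L))
  nbd <- find_class_neighbors(1.2, dup, 0L, k = 3)
  sold <- solve_alpha_linear(nbd, 1.2, lambda_reg = 0)
  expect_true(sold$singular)
  expect_true(all(is.finite(sold$alpha)))
})

test_that("kernel solve with the linear kernel reproduces the linear solve", {
  for (i in 1:20) {
    inst <- random_instance(n = 20, d = 6, seed = 200 + i)
    nb <- find_class_neighbors(inst$query, inst$table, i %% 2L, k = 4)
    lin <- solve_alpha_linear(nb, inst$query, lambda_reg = 1)
    ker <- solve_alpha_kernel(nb, inst$query, kernel_spec("linear"), 1)
    expect_equal(ker$alpha, lin$alpha, tolerance = 1e-8)
    expect_equal(ker$decision_distance_sq, lin$decision_distance_sq,
                 tolerance = 1e-8)
  }
})

test_that("kernel path rejects non-positive regularization", {
  inst <- random_instance(n = 10, d = 3, seed = 5)
  nb <- find_class_neighbors(inst$query, inst$table, 0L, k = 2)
  expect_error(solve_alpha_kernel(nb, inst$query, kernel_spec("rbf", 1), 0),
               "lambda")
})

test_that("classification picks the nearer class and breaks ties low", {
  tab <- feature_table(matrix(c(-10, -9, -8, 8, 9, 10), ncol = 1),
                       c(0L, 0L, 0L, 1L, 1L, 1L))
  prof <- classify(-9.5, tab, k = 2, lambda_reg = 1)
  expect_identical(prof$predicted_class, 0L)
  # perfectly mirrored classes: identical distances, class 0 wins
  mirror <- feature_table(matrix(c(-1, -2, 1, 2), ncol = 1),
                          c(0L, 0L, 1L, 1L))
  prof2 <- classify(0, mirror, k = 2, lambda_reg = 1)
  expect_equal(prof2$per_class_distance_sq[1], prof2$per_class_distance_sq[2])
  expect_identical(prof2$predicted_class, 0L)
})

test_that("k = 1 reduces to per-class nearest neighbor exactly", {
  for (i in 1:10) {
    inst <- random_instance(n = 30, d = 4, seed = 300 + i)
    prof <- classify(inst$query, inst$table, k = 1, lambda_reg = 1)
    nn <- brute_class_nn_sq(inst$query, inst$table)
    expect_identical(prof$per_class_distance_sq, nn)
    expect_identical(prof$predicted_class, which.min(nn) - 1L)
  }
})

test_that("training-row permutation leaves predictions unchanged", {
  set.seed(51)
  inst <- random_instance(n = 40, d = 5, seed = 99)
  q <- inst$query
  perm <- sample(nrow(inst$table$values))
  shuffled <- feature_table(inst$table$values[perm, ], inst$table$labels[perm])
  for (kern in list(NULL, kernel_spec("rbf", 0.5))) {
    p1 <- classify(q, inst$table, k = 3, kern, 1)
    p2 <- classify(q, shuffled, k = 3, kern, 1)
    expect_equal(p1$per_class_distance_sq, p2$per_class_distance_sq,
                 tolerance = 1e-10)
    expect_identical(p1$predicted_class, p2$predicted_class)
  }
})

test_that("with neighbor ties, selection follows row order of the permuted table", {
  # two coincident class-0 points: which row is "the" neighbor follows index
  tab <- feature_table(matrix(c(1, 1, 9, 5, 6), ncol = 1),
                       c(0L, 0L, 0L, 1L, 1L))
  nb1 <- find_class_neighbors(0, tab, 0L, k = 1)
  expect_equal(nb1$row_index, 1L)
  perm_tab <- feature_table(tab$values[c(2, 1, 3, 4, 5), , drop = FALSE],
                            tab$labels[c(2, 1, 3, 4, 5)])
  nb2 <- find_class_neighbors(0, perm_tab, 0L, k = 1)
  expect_equal(nb2$row_index, 1L)   # the earlier row of the permuted order
})

test_that("rescaling one feature can flip a prediction (scale sensitivity)", {
  vals <- rbind(c(0, 0), c(0, 0.02), c(1, 0.00999), c(1, 0.005))
  tab <- feature_table(vals, c(0L, 0L, 1L, 1L))
  q <- c(0.05, 0.01)
  before <- classify(q, tab, k = 1)$predicted_class
  scaled <- feature_table(vals %*% diag(c(1, 1000)), tab$labels)
  after <- classify(q * c(1, 1000), scaled, k = 1)$predicted_class
  expect_identical(before, 0L)
  expect_identical(after, 1L)
})

test_that("batch classification is elementwise and order-preserving", {
  inst <- random_instance(n = 25, d = 4, seed = 77)
  set.seed(78)
  Q <- matrix(rnorm(40), 10, 4)
  batch <- classify_batch(Q, inst$table, k = 3, kernel_spec("rbf", 1), 1)
  expect_length(batch, 10)
  for (i in 1:10) {
    single <- classify(Q[i, ], inst$table, 3, kernel_spec("rbf", 1), 1)
    expect_identical(batch[[i]]$per_class_distance_sq,
                     single$per_class_distance_sq)
  }
  expect_identical(classify_batch(numeric(0), inst$table, 2), list())
  expect_length(classify_batch(Q[1, ], inst$table, 2), 1)
})
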