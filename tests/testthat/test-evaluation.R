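test_that("standardization uses training statistics only and spares binaries", {
  set.seed(81)
  vals <- cbind(rnorm(20, 5, 2), sample(0:1, 20, TRUE))
  colnames(vals) <- c("cont", "bin")
  kinds <- c("continuous", "binary")
  params <- standardize_fit(vals, kinds)
  z <- standardize_apply(vals, params)
  expect_equal(mean(z[, 1]), 0, tolerance = 1e-12)
  expect_equal(sd(z[, 1]), 1, tolerance = 1e-12)
  expect_identical(z[, 2], vals[, 2])
  # a held-out row is transformed with the fitted, not pooled, statistics
  held <- c(100, 1)
  pooled <- standardize_fit(rbind(vals, held), kinds)
  expect_false(isTRUE(all.equal(standardize_apply(held, params),
                                standardize_apply(held, pooled))))
  expect_equal(unname(standardize_apply(held, params)[1]),
               (100 - mean(vals[, 1])) / sd(vals[, 1]))
})

test_that("constant continuous columns pass through with a warning", {
  vals <- cbind(rep(3, 5), 1:5)
  colnames(vals) <- c("flat", "ok")
  expect_warning(params <- standardize_fit(vals, rep("continuous", 2)),
                 "unscaled")
  expect_identical(standardize_apply(vals, params)[, 1], rep(3, 5))
})

test_that("leave-one-out predictions match the per-class 1-NN hand oracle", {
  cfg <- eval_config(k = 1, kernel = NULL, lambda_reg = 1, standardize = FALSE)
  res <- jackknife_evaluate(tiny_1d_table(), cfg)
  expect_equal(res$predictions, c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_equal(res$report$acc, 1)
  # deterministic protocol: identical reruns
  res2 <- jackknife_evaluate(tiny_1d_table(), cfg)
  expect_identical(res$report, res2$report)
  expect_identical(res$distance_sq, res2$distance_sq)
})

test_that("jackknife preconditions and fold failures are enforced", {
  one_class <- feature_table(matrix(rnorm(6), ncol = 2), c(0L, 0L, 0L))
  expect_error(jackknife_evaluate(one_class, eval_config(1)), "two classes")
  singleton <- feature_table(matrix(c(0, 1, 5), ncol = 1), c(0L, 0L, 1L))
  expect_error(jackknife_evaluate(singleton, eval_config(1)), "fold 3")
})

test_that("jackknife through the linear kernel equals the linear path", {
  tab <- generate_blobs(12, dims = 3, separation_sd = 2, seed = 17)
  lin <- jackknife_evaluate(tab, eval_config(3, NULL, 1))
  ker <- jackknife_evaluate(tab, eval_config(3, kernel_spec("linear"), 1))
  expect_identical(lin$predictions, ker$predictions)
  expect_equal(lin$distance_sq, ker$distance_sq, tolerance = 1e-8)
  expect_equal(unclass(lin$report), unclass(ker$report), tolerance = 1e-12)
})

test_that("grid search covers the grid and maximizes finite MCC", {
  tab <- generate_blobs(10, dims = 2, separation_sd = 3, seed = 23)
  res <- grid_search(tab, k_values = 2:3, gamma_values = c(0.25, 1),
                     lambda_reg = 1)
  expect_equal(nrow(res$grid), 4)
  expect_true(is.finite(res$best_mcc))
  expect_equal(res$best_mcc, max(res$grid$mcc[is.finite(res$grid$mcc)]))
  expect_identical(res$criterion, "mcc")
  # single-point grid returns that point
  single <- grid_search(tab, k_values = 2, gamma_values = 0.5)
  expect_equal(nrow(single$grid), 1)
  expect_equal(single$best_k, 2)
  expect_equal(single$best_gamma, 0.5)
})

test_that("NaN MCC never wins and ties prefer smaller k then gamma", {
  tab <- generate_blobs(5, dims = 2, separation_sd = 3, seed = 29)
  fake <- function(table, config) {
    mcc <- if (config$k == 2) NaN else 0.4     # 0.4 tied across gammas at k > 2
    rep <- structure(list(acc = 0.5, sn = 0.5, spec = 0.5, pe = 0.5,
                          npv = 0.5, fscore = 0.5, mcc = mcc),
                     class = "metric_report")
    structure(list(report = rep), class = "jackknife_result")
  }
  testthat::local_mocked_bindings(jackknife_evaluate = fake, .package = "khknn")
  res <- grid_search(tab, k_values = 2:4, gamma_values = c(0.5, 2))
  expect_equal(res$best_k, 3)        # smallest k among the finite ties
  expect_equal(res$best_gamma, 0.5)  # then smallest gamma
  expect_equal(res$best_mcc, 0.4)
  # every configuration NaN: degenerate grid is an error
  all_nan <- function(table, config) {
    rep <- structure(list(acc = NaN, sn = NaN, spec = NaN, pe = NaN,
                          npv = NaN, fscore = NaN, mcc = NaN),
                     class = "metric_report")
    structure(list(report = rep), class = "jackknife_result")
  }
  testthat::local_mocked_bindings(jackknife_evaluate = all_nan,
                                  .package = "khknn")
  expect_error(grid_search(tab, k_values = 2:3, gamma_values = 1),
               "degenerate")
})

test_that("widely separated blobs are recovered almost perfectly", {
  tab <- generate_blobs(30, dims = 5, separation_sd = 6, seed = 31)
  res <- jackknife_evaluate(tab, eval_config(4, kernel_spec("rbf", 2^-3), 1))
  expect_gte(res$report$acc, 0.95)
})
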