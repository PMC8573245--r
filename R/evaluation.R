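#' Evaluation configuration
#'
#' Bundles the classifier settings used by the jackknife protocol:
#' neighborhood size `k`, kernel (or `NULL` for the linear HKNN path),
#' ridge parameter `lambda_reg` (default 1 — a single fixed value keeps
#' the model robust on small cohorts and is the default throughout),
#' whether continuous features are standardized with fold-local
#' statistics, and which label is the positive class.
#'
#' @param k Neighbors per class, `>= 1`.
#' @param kernel `NULL` or a [kernel_spec()]; a kernel requires
#'   `lambda_reg > 0`.
#' @param lambda_reg Ridge parameter (default 1).
#' @param standardize Standardize continuous features within each fold
#'   (default `TRUE`; local-distance methods are scale-sensitive).
#' @param positive_class Label treated as positive (default 1).
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(k, kernel = NULL, lambda_reg = 1,
                        standardize = TRUE, positive_class = 1L) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (!is.null(kernel)) {
    stopifnot(is_kernel_spec(kernel))
    if (lambda_reg <= 0) stop("kernel path requires lambda_reg > 0", call. = FALSE)
  }
  structure(list(k = as.integer(k), kernel = kernel, lambda_reg = lambda_reg,
                 standardize = isTRUE(standardize),
                 positive_class = as.integer(positive_class)),
            class = "eval_config")
}

#' Fit per-feature standardization parameters on training rows
#'
#' Means and standard deviations are computed on the training rows only;
#' binary-kind columns pass through unscaled, as does any continuous
#' column with zero standard deviation (with a warning).
#'
#' @param values Numeric training matrix.
#' @param feature_kinds `"binary"`/`"continuous"` per column.
#' @return List with `center`, `scale` and logical `apply_to`; feed to
#'   [standardize_apply()].
#' @export
standardize_fit <- function(values, feature_kinds) {
  values <- as.matrix(values)
  cont <- feature_kinds == "continuous"
  center <- rep(0, ncol(values))
  scale <- rep(1, ncol(values))
  center[cont] <- colMeans(values[, cont, drop = FALSE])
  sds <- apply(values[, cont, drop = FALSE], 2L, stats::sd)
  zero_sd <- sds == 0 | is.na(sds)
  if (any(zero_sd)) {
    warning("constant continuous column(s) left unscaled: ",
            paste(colnames(values)[cont][zero_sd], collapse = ", "),
            call. = FALSE)
    sds[zero_sd] <- 1
    center[cont][zero_sd] <- 0
  }
  scale[cont] <- sds
  list(center = center, scale = scale, apply_to = cont)
}

#' Apply fitted standardization parameters
#'
#' @param values Numeric matrix (or single row) to transform.
#' @param params Output of [standardize_fit()].
#' @return Matrix of the same shape with continuous columns transformed to
#'   `(x - mean) / sd` under the *fitted* (training) statistics.
#' @export
standardize_apply <- function(values, params) {
  single <- is.null(dim(values))
  if (single) values <- matrix(values, nrow = 1L)
  out <- sweep(sweep(values, 2L, params$center), 2L, params$scale, "/")
  if (single) drop(out) else out
}

#' Leave-one-out (jackknife) evaluation
#'
#' For each sample i, the classifier is built on the remaining n - 1 rows
#' (standardization statistics, when enabled, are refitted on those n - 1
#' rows — held-out rows never leak into the scaling) and predicts row i;
#' the n pooled predictions yield one [compute_metrics()] report. The
#' protocol is deterministic: no randomness, so repeated runs are
#' identical.
#'
#' @param table A [feature_table()] with `n >= 3` and both classes
#'   present.
#' @param config An [eval_config()].
#' @return An object of class `jackknife_result`: `report`
#'   (`metric_report`), `predictions`, `truth`, `distance_sq` (n x C
#'   matrix), `config`.
#' @examples
#' ft <- generate_blobs(15, dims = 2, separation_sd = 6, seed = 7)
#' jackknife_evaluate(ft, eval_config(k = 3, kernel = kernel_spec("rbf", 0.125)))$report
#' @export
jackknife_evaluate <- function(table, config) {
  stopifnot(is_feature_table(table), inherits(config, "eval_config"))
  n <- nrow(table$values)
  if (n < 3L) stop("jackknife needs n >= 3 samples", call. = FALSE)
  if (table$n_classes < 2L) {
    stop("jackknife needs at least two classes in the table", call. = FALSE)
  }
  preds <- integer(n)
  d2 <- matrix(NA_real_, n, table$n_classes)
  for (i in seq_len(n)) {
    train <- subset_rows(table, -i)
    if (length(unique(train$labels)) < table$n_classes) {
      stop(sprintf("fold %d: training part lost a class; jackknife undefined", i),
           call. = FALSE)
    }
    query <- table$values[i, ]
    if (config$standardize) {
      params <- standardize_fit(train$values, train$feature_kinds)
      train <- feature_table(standardize_apply(train$values, params),
                             train$labels, train$feature_names,
                             train$feature_kinds)
      query <- standardize_apply(query, params)
    }
    prof <- classify(query, train, config$k, config$kernel, config$lambda_reg)
    preds[i] <- prof$predicted_class
    d2[i, ] <- prof$per_class_distance_sq
  }
  cc <- confusion_counts(table$labels, preds, config$positive_class)
  structure(list(report = compute_metrics(cc),
                 predictions = preds,
                 truth = table$labels,
                 confusion = cc,
                 distance_sq = d2,
                 config = config),
            class = "jackknife_result")
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf("<jackknife_result> n = %d, k = %d, %s path\n",
              length(x$predictions), x$config$k,
              if (is.null(x$config$kernel)) "linear" else x$config$kernel$family))
  print(x$report)
  invisible(x)
}

#' Grid search over (k, gamma) with lambda fixed
#'
#' Runs [jackknife_evaluate()] with the RBF kernel for every combination
#' of neighborhood size and bandwidth and selects the configuration with
#' the highest *finite* MCC (a NaN MCC — a degenerate predictor — never
#' wins). MCC ties are broken toward smaller k, then smaller gamma,
#' preferring the simpler and smoother model. Defaults follow the
#' protocol used for the cohort study this implements: k from 2 to 8 in
#' steps of 1, gamma over powers of two from 2^-5 to 2^5 (11 values),
#' lambda = 1 — a 7 x 11 = 77-point grid.
#'
#' @param table A [feature_table()].
#' @param k_values Integer vector of neighborhood sizes.
#' @param gamma_values Positive RBF bandwidths.
#' @param lambda_reg Fixed ridge parameter (default 1, `> 0`).
#' @param standardize,positive_class Passed to [eval_config()].
#' @return An object of class `grid_search_result`: `grid` (data frame
#'   with k, gamma and the seven metrics per configuration), `best_k`,
#'   `best_gamma`, `best_mcc`, `criterion = "mcc"`.
#' @export
grid_search <- function(table, k_values = 2:8, gamma_values = 2^(-5:5),
                        lambda_reg = 1, standardize = TRUE,
                        positive_class = 1L) {
  stopifnot(is_feature_table(table))
  if (length(k_values) == 0L || length(gamma_values) == 0L) {
    stop("k_values and gamma_values must be nonempty", call. = FALSE)
  }
  if (lambda_reg <= 0) stop("grid search fixes lambda_reg > 0", call. = FALSE)
  combos <- expand.grid(gamma = gamma_values, k = k_values)[, c("k", "gamma")]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cfg <- eval_config(combos$k[i], kernel_spec("rbf", combos$gamma[i]),
                       lambda_reg, standardize, positive_class)
    r <- jackknife_evaluate(table, cfg)$report
    data.frame(k = combos$k[i], gamma = combos$gamma[i],
               mcc = r$mcc, acc = r$acc, sn = r$sn, spec = r$spec,
               pe = r$pe, npv = r$npv, fscore = r$fscore)
  })
  grid <- do.call(rbind, rows)
  finite <- is.finite(grid$mcc)
  if (!any(finite)) stop("degenerate grid: every configuration has NaN MCC", call. = FALSE)
  cand <- grid[finite, ]
  cand <- cand[order(-cand$mcc, cand$k, cand$gamma), ]
  structure(list(grid = grid,
                 best_k = cand$k[1],
                 best_gamma = cand$gamma[1],
                 best_mcc = cand$mcc[1],
                 criterion = "mcc"),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result> %d configurations; best by %s: k = %d, gamma = %g (MCC = %.4f)\n",
              nrow(x$grid), x$criterion, x$best_k, x$best_gamma, x$best_mcc))
  invisible(x)
}
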