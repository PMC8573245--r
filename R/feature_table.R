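#' Feature table: samples-by-features matrix with class labels
#'
#' The common substrate of the classifier, the jackknife protocol and the
#' synthetic generator: an `n x d` numeric matrix with no missing values,
#' per-column kinds (`"binary"` columns hold only 0/1; `"continuous"`
#' columns are standardized by the evaluation layer), and integer class
#' labels `0, ..., C-1` where every class id occurs at least once.
#'
#' @param values Numeric `n x d` matrix (`n >= 2`, `d >= 1`), no `NA`.
#' @param labels Integer vector of length `n` with values in
#'   `0:(C-1)`; each class id in that range must be present.
#' @param feature_names Character vector of `d` column names; defaults to
#'   `colnames(values)` or `V1..Vd`.
#' @param feature_kinds `"binary"`/`"continuous"` per column; by default
#'   inferred (binary iff the column's value set is a subset of \{0, 1\}).
#' @return An object of class `feature_table` with elements `values`,
#'   `labels`, `feature_names`, `feature_kinds`, `n_classes`.
#' @examples
#' ft <- feature_table(matrix(c(0, 1, 1, 0, 2.5, 3.1, 0.2, 1.4), 4, 2),
#'                     labels = c(0L, 0L, 1L, 1L))
#' ft$feature_kinds
#' @export
feature_table <- function(values, labels, feature_names = NULL,
                          feature_kinds = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric", call. = FALSE)
  storage.mode(values) <- "double"
  n <- nrow(values); d <- ncol(values)
  if (n < 2L || d < 1L) stop("need n >= 2 samples and d >= 1 features", call. = FALSE)
  if (anyNA(values)) stop("feature values must not contain missing entries", call. = FALSE)

  labels <- as.integer(labels)
  if (length(labels) != n || anyNA(labels)) {
    stop("labels must be a complete integer vector of length nrow(values)",
         call. = FALSE)
  }
  if (any(labels < 0L)) stop("class labels must be nonnegative integers", call. = FALSE)
  n_classes <- max(labels) + 1L
  if (!all((seq_len(n_classes) - 1L) %in% labels)) {
    stop("every class id in 0:(C-1) must appear at least once", call. = FALSE)
  }

  if (is.null(feature_names)) feature_names <- colnames(values)
  if (is.null(feature_names)) feature_names <- paste0("V", seq_len(d))
  if (length(feature_names) != d) stop("feature_names length must equal ncol(values)", call. = FALSE)
  colnames(values) <- feature_names

  inferred <- vapply(seq_len(d), function(j) {
    if (all(values[, j] %in% c(0, 1))) "binary" else "continuous"
  }, character(1))
  if (is.null(feature_kinds)) {
    feature_kinds <- inferred
  } else {
    feature_kinds <- match.arg(feature_kinds, c("binary", "continuous"),
                               several.ok = TRUE)
    if (length(feature_kinds) != d) stop("feature_kinds length must equal ncol(values)", call. = FALSE)
    bad <- feature_kinds == "binary" & inferred != "binary"
    if (any(bad)) {
      stop("columns declared binary contain values other than 0/1: ",
           paste(feature_names[bad], collapse = ", "), call. = FALSE)
    }
  }

  structure(list(values = values,
                 labels = labels,
                 feature_names = feature_names,
                 feature_kinds = feature_kinds,
                 n_classes = n_classes),
            class = "feature_table")
}

is_feature_table <- function(x) inherits(x, "feature_table")

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features (%d binary, %d continuous), %d classes\n",
              nrow(x$values), ncol(x$values),
              sum(x$feature_kinds == "binary"),
              sum(x$feature_kinds == "continuous"),
              x$n_classes))
  tab <- table(factor(x$labels, levels = 0:(x$n_classes - 1L)))
  cat("  class counts:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

# Subset rows of a feature table, keeping kinds and names. Used by the
# jackknife folds; does not revalidate class coverage (the caller checks).
subset_rows <- function(table, idx) {
  structure(list(values = table$values[idx, , drop = FALSE],
                 labels = table$labels[idx],
                 feature_names = table$feature_names,
                 feature_kinds = table$feature_kinds,
                 n_classes = table$n_classes),
            class = "feature_table")
}
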