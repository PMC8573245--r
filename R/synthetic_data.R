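#' Per-feature distributional target
#'
#' A continuous feature is specified by its target mean and standard
#' deviation; a binary feature by the proportion of ones. Both carry a
#' target Pearson correlation with the 0/1 cohort label (for binary
#' features the realized point-biserial correlation is attenuated
#' relative to the latent target; the generator targets the latent value
#' and documents, rather than corrects, the attenuation).
#'
#' @param name Feature name.
#' @param mean,sd Target mean and positive SD (continuous).
#' @param positive_proportion Proportion of ones, in (0, 1) (binary).
#' @param target_r Desired correlation with the label, in (-1, 1).
#' @return An object of class `feature_spec`.
#' @export
continuous_feature <- function(name, mean, sd, target_r = 0) {
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  check_target_r(target_r)
  structure(list(name = name, kind = "continuous", mean = mean, sd = sd,
                 target_r = target_r),
            class = "feature_spec")
}

#' @rdname continuous_feature
#' @export
binary_feature <- function(name, positive_proportion, target_r = 0) {
  if (positive_proportion <= 0 || positive_proportion >= 1) {
    stop("positive_proportion must lie in (0, 1)", call. = FALSE)
  }
  check_target_r(target_r)
  structure(list(name = name, kind = "binary",
                 positive_proportion = positive_proportion,
                 target_r = target_r),
            class = "feature_spec")
}

check_target_r <- function(r) {
  if (abs(r) >= 1) stop("target_r must lie strictly inside (-1, 1)", call. = FALSE)
  invisible(r)
}

#' Cohort generation specification
#'
#' Feature targets plus the label design: `n` samples of which exactly
#' `n_positive` carry label 1 (the split is fixed, not a Bernoulli draw —
#' leave-one-out behavior depends on the realized class counts), and a
#' seed making generation fully deterministic.
#'
#' @param features List of [continuous_feature()] / [binary_feature()].
#' @param n Cohort size, `>= 4`.
#' @param n_positive Number of label-1 (high-risk) samples, `0 < n_positive < n`.
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(features, n, n_positive, seed = 1L) {
  stopifnot(all(vapply(features, inherits, logical(1), "feature_spec")))
  if (n < 4L) stop("n must be >= 4", call. = FALSE)
  if (n_positive <= 0L || n_positive >= n) {
    stop("n_positive must satisfy 0 < n_positive < n", call. = FALSE)
  }
  structure(list(features = features, n = as.integer(n),
                 n_positive = as.integer(n_positive), seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default 59-patient ESRD-like cohort specification
#'
#' The transcribed roster of a 59-patient end-stage renal disease cohort
#' used to study cerebrovascular risk: 32 mixed binary/continuous
#' features (demographics, comorbidities, blood chemistry, CKD-MBD
#' markers, nutritional and calcification indices, stroke scores) with
#' their published means/SDs or proportions and Pearson correlations
#' against the dichotomized risk-group label (25 low-risk / 34
#' high-risk). The real cohort is not publicly deposited; cohorts drawn
#' from this specification are synthetic stand-ins with matching
#' marginal summaries, not patient data.
#'
#' @param seed Seed stored in the returned spec (default 1).
#' @return A [cohort_spec()] with `n = 59`, `n_positive = 34`.
#' @export
default_cohort_spec <- function(seed = 1L) {
  f <- list(
    binary_feature("sex_male", 32 / 59, -0.0455),
    continuous_feature("age", 55.83, 15.60, 0.4010),
    binary_feature("smoking", 1 / 59, -0.0847),
    continuous_feature("bmi", 23.56, 3.12, 0.1639),
    binary_feature("diabetes", 24 / 59, 0.4847),
    binary_feature("cerebral_ischemia", 3 / 59, 0.0025),
    binary_feature("coronary_heart_disease", 5 / 59, 0.0433),
    continuous_feature("systolic_bp", 155.69, 23.63, -0.1150),
    continuous_feature("diastolic_bp", 88.11, 13.71, -0.2043),
    binary_feature("phosphate_binder", 36 / 59, -0.2141),
    continuous_feature("hemoglobin", 85.38, 18.12, -0.2584),
    continuous_feature("c_reactive_protein", 11.74, 35.61, 0.3016),
    continuous_feature("serum_creatinine", 785.09, 368.62, -0.4252),
    continuous_feature("serum_glucose", 5.48, 2.28, 0.2608),
    continuous_feature("serum_calcium", 2.08, 0.24, 0.0520),
    continuous_feature("serum_phosphorus", 1.81, 0.38, -0.0862),
    continuous_feature("total_glyceride", 1.69, 1.08, -0.0542),
    continuous_feature("total_cholesterol", 4.53, 1.42, -0.0466),
    continuous_feature("ldl_c", 2.45, 0.96, -0.0252),
    continuous_feature("hdl_c", 0.97, 0.55, 0.0866),
    continuous_feature("hba1c", 5.82, 1.03, 0.2151),
    continuous_feature("serum_albumin", 34.31, 6.61, -0.1308),
    continuous_feature("vitamin_d3_25oh", 7.86, 4.55, 0.3850),
    continuous_feature("ipth", 274.50, 306.31, -0.0225),
    continuous_feature("gnri", 96.06, 12.76, -0.0078),
    continuous_feature("fgf23", 32.21, 53.02, -0.0966),
    continuous_feature("klotho", 2.38, 2.33, 0.0443),
    continuous_feature("interleukin_6", 25.37, 53.69, 0.2634),
    continuous_feature("fetuin_a", 3.0320e5, 2.0606e5, -0.0234),
    continuous_feature("aacs", 1.95, 1.55, 0.2113),
    continuous_feature("chads2", 1.93, 1.11, 0.4247),
    continuous_feature("cha2ds2_vasc", 2.79, 1.50, 0.5097)
  )
  cohort_spec(f, n = 59L, n_positive = 34L, seed = seed)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic cohort from a specification
#'
#' Labels are a random permutation of exactly `n_positive` ones and
#' `n - n_positive` zeros. Each feature is drawn from a single-latent-
#' factor construction: with `s` the standardized label and `eps`
#' independent standard normal noise, the latent value is
#' `z = target_r * s + sqrt(1 - target_r^2) * eps`. Continuous features
#' are affinely mapped to the target mean/SD; binary features are
#' thresholded at the Gaussian quantile matching `positive_proportion`.
#' Features are mutually correlated only through the label (no
#' feature-feature correlation targets are imposed). Generation is a
#' pure function of the spec, including its seed; the caller's RNG state
#' is left untouched.
#'
#' @param spec A [cohort_spec()].
#' @param floor_at_zero Clamp negative continuous draws to 0 (default
#'   `FALSE`: clamping biases the realized mean upward for heavy-tailed
#'   quantities whose published SD exceeds their mean, so the default
#'   preserves the targeted moments at the price of occasional negative
#'   values).
#' @return A [feature_table()] with 0/1 labels (1 = high-risk).
#' @export
generate_cohort <- function(spec, floor_at_zero = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    y <- sample(c(rep(1L, spec$n_positive), rep(0L, n - spec$n_positive)))
    s <- (y - mean(y)) / stats::sd(y)
    cols <- lapply(spec$features, function(fs) {
      r <- fs$target_r
      z <- r * s + sqrt(1 - r^2) * stats::rnorm(n)
      if (fs$kind == "continuous") {
        x <- fs$mean + fs$sd * z
        if (floor_at_zero) x <- pmax(x, 0)
        x
      } else {
        as.numeric(z >= stats::qnorm(1 - fs$positive_proportion))
      }
    })
    values <- do.call(cbind, cols)
    colnames(values) <- vapply(spec$features, `[[`, character(1), "name")
    kinds <- vapply(spec$features, `[[`, character(1), "kind")
    feature_table(values, y, feature_kinds = kinds)
  })
}

#' Generate a two-class Gaussian blob benchmark
#'
#' Two spherical unit-variance Gaussian classes in `dims` dimensions,
#' centers `separation_sd` standard deviations apart along the first
#' axis. Class 0 is centered at the origin, class 1 at
#' `(separation_sd, 0, ..., 0)`. A sanity fixture: with wide separation
#' any reasonable classifier should approach perfect leave-one-out
#' accuracy; with zero separation, chance.
#'
#' @param n_per_class Samples per class, `>= 2`.
#' @param dims Dimensionality, `>= 1`.
#' @param separation_sd Center separation in SD units, `>= 0`.
#' @param seed Integer RNG seed.
#' @return A [feature_table()] with `2 * n_per_class` rows.
#' @export
generate_blobs <- function(n_per_class, dims, separation_sd, seed = 1L) {
  if (n_per_class < 2L || dims < 1L) {
    stop("need n_per_class >= 2 and dims >= 1", call. = FALSE)
  }
  with_seed(seed, {
    x0 <- matrix(stats::rnorm(n_per_class * dims), n_per_class, dims)
    x1 <- matrix(stats::rnorm(n_per_class * dims), n_per_class, dims)
    x1[, 1] <- x1[, 1] + separation_sd
    feature_table(rbind(x0, x1),
                  c(rep(0L, n_per_class), rep(1L, n_per_class)),
                  feature_names = paste0("x", seq_len(dims)))
  })
}
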