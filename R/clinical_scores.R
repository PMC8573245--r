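#' Patient record for clinical risk scoring
#'
#' Holds the inputs of the CHADS2, CHA2DS2-VASc, GNRI and abdominal
#' aortic calcification score (AACS) calculators.
#'
#' @param age Age in years (nonnegative).
#' @param sex `"male"` or `"female"`.
#' @param chf Congestive heart failure (logical).
#' @param hypertension,diabetes Logical comorbidity flags.
#' @param stroke_or_tia Prior stroke or transient ischemic attack.
#' @param vascular_disease Vascular disease (CHA2DS2-VASc only).
#' @param albumin_g_dl Serum albumin in g/dl (see [albumin_gl_to_gdl()]
#'   if your laboratory reports g/L).
#' @param weight_ratio Actual / ideal body weight (dimensionless; ideal
#'   body weight is an input, not computed here).
#' @param aac_fractions Eight calcified-length fractions in \[0, 1\]:
#'   anterior and posterior aortic walls at lumbar levels L1-L4.
#' @return An object of class `patient_record`.
#' @examples
#' p <- patient_record(age = 80, sex = "female", hypertension = TRUE,
#'                     stroke_or_tia = TRUE)
#' chads2_score(p)
#' cha2ds2_vasc_score(p)
#' @export
patient_record <- function(age, sex = c("male", "female"), chf = FALSE,
                           hypertension = FALSE, diabetes = FALSE,
                           stroke_or_tia = FALSE, vascular_disease = FALSE,
                           albumin_g_dl = NA_real_, weight_ratio = NA_real_,
                           aac_fractions = rep(0, 8)) {
  sex <- match.arg(sex)
  if (!is.numeric(age) || length(age) != 1L || is.na(age) || age < 0) {
    stop("age must be a single nonnegative number", call. = FALSE)
  }
  if (length(aac_fractions) != 8L) {
    stop("aac_fractions must have exactly 8 entries (anterior/posterior x L1-L4)",
         call. = FALSE)
  }
  if (anyNA(aac_fractions) || any(aac_fractions < 0 | aac_fractions > 1)) {
    stop("aac_fractions must lie in [0, 1]", call. = FALSE)
  }
  flags <- c(chf = chf, hypertension = hypertension, diabetes = diabetes,
             stroke_or_tia = stroke_or_tia, vascular_disease = vascular_disease)
  if (!all(vapply(flags, is.logical, logical(1)))) {
    stop("comorbidity flags must be logical", call. = FALSE)
  }
  structure(list(age = age, sex = sex, chf = isTRUE(chf),
                 hypertension = isTRUE(hypertension),
                 diabetes = isTRUE(diabetes),
                 stroke_or_tia = isTRUE(stroke_or_tia),
                 vascular_disease = isTRUE(vascular_disease),
                 albumin_g_dl = albumin_g_dl, weight_ratio = weight_ratio,
                 aac_fractions = as.numeric(aac_fractions)),
            class = "patient_record")
}

#' CHADS2 stroke-risk score
#'
#' One point each for congestive heart failure, hypertension, age >= 75
#' years and diabetes mellitus; two points for a history of stroke or
#' transient ischemic attack. Range 0-6.
#'
#' @param p A [patient_record()].
#' @return Integer score in 0..6.
#' @export
chads2_score <- function(p) {
  stopifnot(inherits(p, "patient_record"))
  as.integer(p$chf + p$hypertension + (p$age >= 75) + p$diabetes +
               2L * p$stroke_or_tia)
}

#' CHA2DS2-VASc stroke-risk score
#'
#' One point each for congestive heart failure, hypertension, diabetes,
#' vascular disease, female sex and age 65-74; two points each for age
#' >= 75 (the two age bands are mutually exclusive) and a history of
#' stroke or transient ischemic attack. Range 0-9.
#'
#' @param p A [patient_record()].
#' @return Integer score in 0..9.
#' @export
cha2ds2_vasc_score <- function(p) {
  stopifnot(inherits(p, "patient_record"))
  age_pts <- if (p$age >= 75) 2L else if (p$age >= 65) 1L else 0L
  as.integer(p$chf + p$hypertension + p$diabetes + p$vascular_disease +
               (p$sex == "female") + age_pts + 2L * p$stroke_or_tia)
}

#' Dichotomize a stroke-risk score into risk groups
#'
#' Scores of 0-1 form the low-risk group; scores >= 2 the high-risk
#' group.
#'
#' @param score Nonnegative integer score (vectorized).
#' @return `"low"` or `"high"` per score.
#' @export
risk_group <- function(score) {
  if (any(score < 0)) stop("score must be nonnegative", call. = FALSE)
  ifelse(score <= 1, "low", "high")
}

#' Geriatric Nutritional Risk Index
#'
#' `GNRI = 14.89 x serum albumin (g/dl) + 41.7 x (actual / ideal body
#' weight)`. Albumin must be supplied in g/dl; laboratory values reported
#' in g/L should be divided by 10 first ([albumin_gl_to_gdl()]). A value
#' above 10 g/dl is physiologically implausible and triggers a warning,
#' since it usually means a g/L value slipped through unconverted.
#'
#' @param albumin_g_dl Serum albumin in g/dl, `>= 0`.
#' @param weight_ratio Actual / ideal body weight, `>= 0`.
#' @return The index (dimensionless; values around 100 are typical for
#'   well-nourished adults).
#' @examples
#' gnri(4.0, 1.0)  # 101.26
#' @export
gnri <- function(albumin_g_dl, weight_ratio) {
  if (any(albumin_g_dl < 0) || any(weight_ratio < 0)) {
    stop("gnri inputs must be nonnegative", call. = FALSE)
  }
  if (any(albumin_g_dl > 10)) {
    warning("albumin > 10 g/dl is implausible; was the value in g/L? ",
            "Convert with albumin_gl_to_gdl().", call. = FALSE)
  }
  14.89 * albumin_g_dl + 41.7 * weight_ratio
}

#' Convert serum albumin from g/L to g/dl
#' @param albumin_g_l Albumin in g/L.
#' @return Albumin in g/dl.
#' @export
albumin_gl_to_gdl <- function(albumin_g_l) albumin_g_l / 10

#' Score one aortic wall segment from its calcified-length fraction
#'
#' 0 points for no calcification; 1 point for calcification over less
#' than one-third of the wall length; 2 points between one-third and
#' two-thirds; 3 points for more than two-thirds. The boundary fractions
#' exactly 1/3 and 2/3 fall in the middle band (score 2): the verbal
#' bands leave the boundaries open, so the middle interval is taken
#' closed.
#'
#' @param fraction Calcified fraction(s) of the wall length, in \[0, 1\].
#' @return Integer segment score(s) in 0..3.
#' @export
aac_segment_score <- function(fraction) {
  if (any(is.na(fraction)) || any(fraction < 0 | fraction > 1)) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  ifelse(fraction == 0, 0L,
         ifelse(fraction < 1 / 3, 1L,
                ifelse(fraction <= 2 / 3, 2L, 3L)))
}

#' Total abdominal aortic calcification score (AACS)
#'
#' Sums the 0-3 segment scores over the eight wall segments (anterior
#' and posterior walls at L1-L4), giving a total of 0-24 points.
#'
#' @param p A [patient_record()] with its 8 `aac_fractions`.
#' @return Integer total in 0..24.
#' @export
aacs_total <- function(p) {
  stopifnot(inherits(p, "patient_record"))
  sum(aac_segment_score(p$aac_fractions))
}
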