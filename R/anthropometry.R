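#' Du Bois body surface area
#'
#' BSA = 0.007184 x BWT^0.425 x HT^0.725, with weight in kg and height in cm.
#' @param bwt body weight, kg (>= 0)
#' @param ht height, cm (> 0)
#' @return body surface area in m^2
#' @export
bsa_du_bois <- function(bwt, ht) {
  if (any(bwt < 0) || any(ht <= 0)) stop("bwt must be >= 0 and ht > 0")
  0.007184 * bwt^0.425 * ht^0.725
}

#' Growth z-score
#'
#' (observed - median of the reference population) / SD of the reference
#' population.
#' @param observed observed value
#' @param median reference median
#' @param sd reference SD (> 0)
#' @return z-score
#' @export
z_score <- function(observed, median, sd) {
  if (any(sd <= 0)) stop("reference sd must be positive")
  (observed - median) / sd
}

#' Growth reference lookup
#'
#' Median and SD of weight-for-height (by height in cm) or weight-for-age
#' (by age in months) from the embedded WHO-standards-like tables, linearly
#' interpolated on the grid. The simple median/SD form is deliberate: the
#' z-score definition used here needs nothing more.
#'
#' @param sex "male" or "female"
#' @param height_cm height for a weight-for-height lookup
#' @param age_months age for a weight-for-age lookup (give exactly one of
#'   the two)
#' @return list with elements `median` and `sd` (kg)
#' @export
growth_reference <- function(sex, height_cm = NULL, age_months = NULL) {
  if (is.null(height_cm) == is.null(age_months)) {
    stop("give exactly one of height_cm or age_months")
  }
  if (!is.null(height_cm)) {
    tab <- .cached_csv("wfh", "growth_reference_wfh.csv")
    tab <- tab[tab$sex == sex, ]
    list(median = approx(tab$height_cm, tab$median_kg, height_cm, rule = 2)$y,
         sd = approx(tab$height_cm, tab$sd_kg, height_cm, rule = 2)$y)
  } else {
    tab <- .cached_csv("wfa", "growth_reference_wfa.csv")
    tab <- tab[tab$sex == sex, ]
    list(median = approx(tab$age_months, tab$median_kg, age_months, rule = 2)$y,
         sd = approx(tab$age_months, tab$sd_kg, age_months, rule = 2)$y)
  }
}

#' Weight-for-height z-score of a virtual individual
#'
#' Uses the model body weight and height directly (no measurement noise).
#' @param individual a `physiology` object
#' @return WHZ
#' @export
whz <- function(individual) {
  ref <- growth_reference(individual$sex, height_cm = individual$ht)
  z_score(individual$bwt, ref$median, ref$sd)
}

#' Weight-for-age z-score of a virtual individual
#' @param individual a `physiology` object
#' @return WAZ
#' @export
waz <- function(individual) {
  ref <- growth_reference(individual$sex, age_months = individual$age * 12)
  z_score(individual$bwt, ref$median, ref$sd)
}

#' Classify severe acute malnutrition from WHZ
#'
#' Severe iff weight-for-height z-score is strictly below -3 (the
#' mid-upper-arm-circumference branch of the clinical criterion has no
#' anatomical surrogate in the model and is not evaluated).
#' @param whz weight-for-height z-score (finite)
#' @return "severe" or "not-severe"
#' @export
classify_sam <- function(whz) {
  stopifnot(all(is.finite(whz)))
  ifelse(whz < -3, "severe", "not-severe")
}
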