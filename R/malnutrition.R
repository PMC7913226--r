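#' Derive a physiological scaling parameter
#'
#' The double ratio PSP = (X_rM / X_tM) / (X_rN / X_tN), where X_r are
#' reported measurements and X_t the height-conditional typical reference
#' values, for the malnourished (M) and non-malnourished (N) groups. With
#' equal typical values this reduces to the plain malnourished-to-reference
#' measurement ratio.
#'
#' @param reported_malnourished,reported_normal reported measurements
#' @param typical_malnourished,typical_normal typical (reference) values at
#'   the study populations' heights; default 1 (equal typicals)
#' @return dimensionless scaling factor
#' @export
derive_psp <- function(reported_malnourished, reported_normal,
                       typical_malnourished = 1, typical_normal = 1) {
  v <- c(reported_malnourished, reported_normal,
         typical_malnourished, typical_normal)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("all measurements must be positive and finite")
  }
  (reported_malnourished / typical_malnourished) /
    (reported_normal / typical_normal)
}

#' Interpolate a scaling factor to a milder malnutrition level
#'
#' Linear interpolation of the deficit (1 - factor) on the
#' percent-of-standard body-weight/height scale: the factor deficit at a
#' target level is the severe deficit multiplied by the target's
#' percent-of-standard shortfall relative to the severe shortfall.
#'
#' @param severe_factor scaling factor at severe malnutrition
#' @param pct_standard_target percent-of-standard BWT/HT at the target level
#' @param pct_standard_severe percent-of-standard BWT/HT at severe (73.9)
#' @return interpolated factor
#' @export
interpolate_level <- function(severe_factor, pct_standard_target,
                              pct_standard_severe = 73.9) {
  stopifnot(severe_factor > 0, pct_standard_target > 0,
            pct_standard_target <= 100, pct_standard_severe > 0,
            pct_standard_severe <= 100)
  if (pct_standard_severe == 100) {
    stop("severe percent-of-standard of 100 leaves the deficit undefined")
  }
  1 + (severe_factor - 1) *
    (100 - pct_standard_target) / (100 - pct_standard_severe)
}

#' Skin scaling factor from body surface area
#'
#' Skin mass is scaled with the Du Bois body surface area at fixed height,
#' so the factor is the body-weight ratio raised to the Du Bois weight
#' exponent 0.425 (the height term cancels).
#'
#' @param bwt_malnourished,bwt_normal body weights, kg
#' @return dimensionless skin factor
#' @export
skin_psp <- function(bwt_malnourished, bwt_normal) {
  if (bwt_malnourished <= 0 || bwt_normal <= 0) {
    stop("body weights must be positive")
  }
  (bwt_malnourished / bwt_normal)^0.425
}

# Reference hematocrit (in the units of the study table) back-derived
# consistently from all three level pairs of the shipped factor table.
.REF_HEMATOCRIT <- 47
# Reference serum albumin, g/100 mL, in non-malnourished male adults.
.REF_ALBUMIN <- 4.25

#' Build the three-level scaling-parameter table
#'
#' Derives every factor that the reference-study measurements support:
#' plasma proteins (serum albumin over the 4.25 g/100 mL reference; the
#' alpha-1-acid glycoprotein factor is set equal to the albumin factor),
#' hematocrit (over reference 47), skin (Du Bois weight exponent on the
#' percent-of-standard body-weight ratio) and the linear level
#' interpolation of the organ factors from their severe values. Factors
#' whose height-adjusted typical values cannot be reconstructed (the
#' severe organ factors, blood compartments, fat and muscle) come from the
#' shipped factor table. The fat and muscle factors are then jointly
#' re-adjusted by a single multiplier so that applying the severe set to
#' the reference adult man closes the organ-mass sum on the
#' percent-of-standard body weight (73.9% of 73.0 kg), preserving the
#' fat-to-muscle weight ratio; the same closure is applied per level.
#'
#' @param reference the individual used for the fat/muscle mass-balance
#'   closure (default: the 30-year-old reference man)
#' @return named list of `psp_set` objects for levels mild, intermediate
#'   and severe; each has `level`, `factors` (one per compartment plus
#'   `plasma_proteins` and `hematocrit`) and `provenance`
#' @export
build_psp_table <- function(reference = reference_individual(30, "male")) {
  t1 <- reference_study_table()
  fix <- psp_fixture_table()
  levels <- c("mild", "intermediate", "severe")
  get1 <- function(meas, cat) {
    v <- t1$value[t1$measurement == meas & t1$category == cat]
    if (length(v) != 1L) stop("reference-study fixture missing ", meas)
    v
  }
  pct <- vapply(levels, function(l) get1("pct_standard_bwt_ht", l), numeric(1))

  fixture_sets <- lapply(levels, function(l) {
    setNames(fix[[l]], fix$compartment)
  })
  names(fixture_sets) <- levels
  prov0 <- setNames(fix$provenance, fix$compartment)

  out <- lapply(levels, function(l) {
    f <- fixture_sets[[l]]
    prov <- prov0
    # measured hematological and protein factors
    f["plasma_proteins"] <- derive_psp(get1("serum_albumin_g_100mL", l),
                                       .REF_ALBUMIN)
    f["hematocrit"] <- derive_psp(get1("hematocrit", l), .REF_HEMATOCRIT)
    f["skin"] <- skin_psp(pct[[l]], 100)
    prov[c("plasma_proteins", "hematocrit")] <- "measured"
    prov["skin"] <- "measured"
    if (l != "severe") {
      # organ factors interpolated from their severe values on the
      # percent-of-standard deficit scale
      for (cp in c("bone", "brain", "gonads", "intestines", "lung",
                   "stomach", "heart", "kidney", "liver", "pancreas",
                   "spleen")) {
        f[cp] <- interpolate_level(fixture_sets$severe[[cp]], pct[[l]],
                                   pct[["severe"]])
        prov[cp] <- "interpolated"
      }
    }
    # fat/muscle closure on the reference man at this level's target BWT
    m <- reference$organ_masses
    target <- reference$bwt * pct[[l]] / 100
    fm <- c("fat", "muscle")
    others <- setdiff(names(m), fm)
    mult <- (target - sum(m[others] * f[others])) / sum(m[fm] * f[fm])
    adj <- pmin(1, f[fm] * mult)
    if (any(f[fm] * mult > 1)) {
      warning("fat/muscle closure multiplier capped at a factor of 1")
    }
    f[fm] <- adj
    prov[fm] <- "adjusted"
    structure(list(level = l, factors = f, provenance = prov),
              class = "psp_set")
  })
  names(out) <- levels
  out
}

#' @export
print.psp_set <- function(x, ...) {
  cat(sprintf("<psp_set> level %s\n", x$level))
  print(round(x$factors, 3))
  invisible(x)
}

#' Identity (non-malnourished) scaling set
#' @return a `psp_set` with every factor equal to 1
#' @export
psp_identity <- function() {
  f <- setNames(rep(1, length(compartment_names()) + 2),
                c(compartment_names(), "plasma_proteins", "hematocrit"))
  structure(list(level = "none", factors = f,
                 provenance = setNames(rep("fixture", length(f)), names(f))),
            class = "psp_set")
}

#' Apply a malnutrition scaling set to an individual
#'
#' Each compartment mass is multiplied by its factor; plasma protein
#' concentrations (albumin, alpha-1-acid glycoprotein) by the
#' plasma-protein factor; hematocrit by its factor. Specific perfusion
#' (flow per kg tissue) is preserved, so absolute organ blood flows -- and
#' with them cardiac output -- shrink with organ mass. The glomerular
#' filtration rate follows kidney mass. Body weight is recomputed as the
#' scaled organ-mass sum; height, age, sex and ontogeny are unchanged.
#'
#' @param individual a `physiology` object
#' @param psps a `psp_set`
#' @return the scaled `physiology`
#' @export
apply_psps <- function(individual, psps) {
  stopifnot(inherits(individual, "physiology"), inherits(psps, "psp_set"))
  f <- psps$factors
  missing <- setdiff(names(individual$organ_masses), names(f))
  if (length(missing)) {
    stop("scaling set lacks factors for: ", paste(missing, collapse = ", "))
  }
  out <- individual
  out$organ_masses <- individual$organ_masses *
    f[names(individual$organ_masses)]
  out$bwt <- sum(out$organ_masses)
  out$hematocrit <- individual$hematocrit * f[["hematocrit"]]
  out$albumin <- individual$albumin * f[["plasma_proteins"]]
  out$agp <- individual$agp * f[["plasma_proteins"]]
  out$gfr <- individual$gfr * f[["kidney"]]
  out$malnutrition <- psps$level
  out$plasma_protein_factor <-
    f[["plasma_proteins"]] * .protein_factor_of(individual)
  out
}

.protein_factor_of <- function(individual) {
  pf <- individual$plasma_protein_factor
  if (is.null(pf)) 1 else pf
}

#' Scale the unbound plasma fraction with plasma-protein levels
#'
#' Standard binding-protein proportionality: with the bound:free ratio
#' proportional to protein concentration, fu' = 1 / (1 + (1 - fu)/fu * r)
#' where r is the plasma-protein scaling factor.
#' @param fu_p unbound fraction at reference protein levels
#' @param protein_factor relative plasma-protein concentration r
#' @return adjusted unbound fraction
#' @export
scale_fu <- function(fu_p, protein_factor) {
  stopifnot(fu_p > 0, fu_p <= 1, protein_factor > 0)
  1 / (1 + (1 - fu_p) / fu_p * protein_factor)
}
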