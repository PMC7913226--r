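#' Names of the shipped drug models
#' @return character vector
#' @export
drug_names <- function() {
  sort(sub("\\.yaml$", "", list.files(.extdata("drugs"), pattern = "\\.yaml$")))
}

.drug_required <- c("name", "logP", "fu_p", "mw", "pka", "solubility",
                    "distribution")

#' Load and validate a drug model
#'
#' Reads one of the shipped drug parameter files (or any user-supplied
#' config in the same schema) and validates it. Fields mirror the final
#' model parameter sets: physico-chemistry (logP, molecular weight, pKa
#' list), plasma binding (fu_p), solubility by prandial state, the
#' partition-coefficient method, intestinal permeability (1e-6 cm/min),
#' renal elimination (GFR fraction and/or kidney-volume-normalized specific
#' clearance, 1/min), hepatic elimination (Michaelis-Menten Vmax
#' [pmol/min/mg microsomal protein] with Km [uM], liver-volume-normalized
#' specific clearance [1/min], or intrinsic clearance [uL/min/mg]), biliary
#' specific clearance, erythrocyte protein/lipid volume fractions, and
#' optional per-segment absorption surface enhancement overrides.
#'
#' @param name a shipped drug name (see `drug_names()`) or a path to a
#'   YAML config
#' @return a validated `drug_model` list
#' @export
load_drug <- function(name) {
  path <- if (file.exists(name)) name else .extdata("drugs", paste0(name, ".yaml"))
  if (!file.exists(path)) stop("unknown drug or missing config: ", name)
  d <- yaml::read_yaml(path)
  validate_drug(d)
}

#' @rdname load_drug
#' @param drug a raw drug parameter list
#' @export
validate_drug <- function(drug) {
  missing <- setdiff(.drug_required, names(drug))
  if (length(missing)) {
    stop("drug config invalid; missing field(s): ",
         paste(missing, collapse = ", "))
  }
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(is.numeric(drug$fu_p) && drug$fu_p > 0 && drug$fu_p <= 1,
      "fu_p must be in (0, 1]")
  chk(is.numeric(drug$logP), "logP must be numeric")
  chk(is.numeric(drug$mw) && drug$mw > 0, "mw must be positive")
  chk(is.list(drug$pka) &&
        all(vapply(drug$pka, function(p)
          is.numeric(p$value) && p$type %in% c("acid", "base"), logical(1))),
      "pka must be a list of {value, type acid|base}")
  chk(is.list(drug$solubility) &&
        all(vapply(drug$solubility, function(s)
          is.numeric(s$mg_mL) && s$mg_mL > 0, logical(1))),
      "solubility entries must have positive mg_mL")
  chk(drug$distribution %in% c("pksim", "rodgers_rowland", "schmitt"),
      "distribution must be pksim, rodgers_rowland or schmitt")
  if (!is.null(drug$renal)) {
    chk(all(unlist(drug$renal[c("cl_spec", "gfr_fraction")]) >= 0,
            na.rm = TRUE), "renal clearance terms must be non-negative")
  }
  if (length(problems)) {
    stop("drug config invalid: ", paste(problems, collapse = "; "))
  }
  structure(drug, class = "drug_model")
}

#' Solubility for a prandial state
#' @param drug a `drug_model`
#' @param prandial "fasted", "fed" or "fed_high_fat"
#' @return solubility in mg/mL
#' @export
drug_solubility <- function(drug, prandial = "fasted") {
  states <- vapply(drug$solubility, function(s) s$prandial %||% "any",
                   character(1))
  hit <- which(states == prandial)
  if (!length(hit)) hit <- which(states == "any")
  if (!length(hit)) stop("no solubility for prandial state ", prandial)
  drug$solubility[[hit[1]]]$mg_mL
}

#' Meal model
#' @param volume_mL drink volume, mL
#' @param kcal caloric content
#' @return a `meal` list
#' @export
meal_model <- function(volume_mL, kcal) {
  stopifnot(volume_mL >= 0, kcal >= 0)
  list(volume_mL = volume_mL, kcal = kcal)
}

#' Administration setup replicating a named reference simulation
#'
#' Returns the formulation, prandial state, dose rule and population ages
#' of the registered study setups ("development" for the adult reference
#' simulations, "pediatric" for the malnourished pediatric studies).
#'
#' @param drug drug name or `drug_model`
#' @param study registry key, e.g. "pediatric" or "development"
#' @return a `study_setup` list with fields `route`, `dose_mg`,
#'   `dose_mg_kg`, `prandial`, `meal`, `age_range_y`, `sim_hours`,
#'   `matrix`, `dissolution`, `particle_radius_um`, `infusion_min`
#' @export
formulation_for_study <- function(drug, study = "pediatric") {
  name <- if (inherits(drug, "drug_model")) drug$name else drug
  reg <- .maln$studies
  if (is.null(reg)) {
    reg <- .maln$studies <- yaml::read_yaml(.extdata("studies.yaml"))
  }
  if (is.null(reg[[name]]) || is.null(reg[[name]][[study]])) {
    stop("unknown study '", study, "' for drug '", name, "'")
  }
  setup <- reg[[name]][[study]]
  d <- if (inherits(drug, "drug_model")) drug else load_drug(name)
  if (setup$route %in% c("oral_solid")) {
    key <- if (!is.null(d$dissolution[[setup$prandial]])) setup$prandial
           else "any"
    w <- d$dissolution[[key]]
    if (is.null(w)) stop("drug ", name, " lacks a dissolution law")
    setup$dissolution <- weibull_dissolution(w$t50_min / 60, w$shape)
  } else if (setup$route == "oral_suspension") {
    setup$dissolution <- particle_dissolution(setup$particle_radius_um)
  }
  setup$drug <- name
  setup$study <- study
  structure(setup, class = "study_setup")
}
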