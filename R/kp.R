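# Tissue:plasma partition coefficient (Kp) prediction from tissue
# composition, plus the whole-blood/plasma concentration ratio.

.as_composition <- function(tissue) {
  if (is.character(tissue)) tissue <- tissue_composition(tissue)
  as.list(tissue)
}

# Combined ionization factor 1 + sum of charged:neutral ratios at a pH.
.ionization <- function(pka, ph) {
  I <- 1
  for (p in pka) {
    I <- I + if (p$type == "base") 10^(p$value - ph) else 10^(ph - p$value)
  }
  I
}

.fraction_neutral <- function(pka, ph) 1 / .ionization(pka, ph)

# Vegetable-oil:water partition used for neutral lipid in adipose.
.log_p_vow <- function(logp) 1.115 * logp - 1.35

#' Rodgers-Rowland tissue:plasma partition coefficient
#'
#' Composition-based Kp prediction. Moderate-to-strong bases (a basic pKa
#' of 7 or above) partition into acidic phospholipids with an association
#' constant back-calculated from blood-cell partitioning; acids, neutrals
#' and weak bases bind extracellular albumin via the tissue:plasma albumin
#' ratio. Neutral-lipid partitioning uses the octanol scale, except in
#' adipose where the vegetable-oil:water scale applies.
#'
#' @param drug a `drug_model`, or a list with `logP`, `fu_p` and `pka`
#' @param tissue a compartment name or a composition row/list
#' @param fu_p unbound plasma fraction (defaults to the drug's)
#' @param kpu_bc unbound blood-cell partition used to anchor the
#'   acidic-phospholipid association of strong bases; defaults to a
#'   blood-cell:plasma concentration ratio of 1, i.e. `1/fu_p`
#' @return Kp (tissue:plasma, dimensionless, > 0)
#' @export
kp_rodgers_rowland <- function(drug, tissue, fu_p = drug$fu_p,
                               kpu_bc = 1 / fu_p) {
  tc <- .as_composition(tissue)
  pl <- .as_composition("plasma")
  pka <- drug$pka %||% list()
  base_pkas <- vapply(pka, function(p) if (p$type == "base") p$value else -Inf,
                      numeric(1))
  strong_base <- length(base_pkas) && max(base_pkas) >= 7
  if (strong_base && length(pka) > 1) {
    stop("unsupported multi-ionization combination: a moderate-to-strong ",
         "base with additional ionizable groups")
  }
  is_adipose <- identical(tc$tissue, "adipose")
  P <- 10^(if (is_adipose) .log_p_vow(drug$logP) else drug$logP)
  Pnp <- 0.3 * P + 0.7
  ph_iw <- tc$ph_iw %||% 7
  ph_p <- 7.4

  if (strong_base) {
    pka_b <- max(base_pkas)
    Y <- 1 + 10^(pka_b - ph_p)
    X <- 1 + 10^(pka_b - ph_iw)
    bc <- .as_composition("rbc")
    Xbc <- 1 + 10^(pka_b - bc$ph_iw)
    Pbc <- 10^drug$logP
    ka_ap <- (kpu_bc - Xbc / Y * bc$f_iw -
                (Pbc * bc$f_nl + (0.3 * Pbc + 0.7) * bc$f_np) / Y) *
      Y / (bc$ap_mg_g * 10^(pka_b - bc$ph_iw))
    ka_ap <- max(0, ka_ap)
    kpu <- tc$f_ew + X / Y * tc$f_iw +
      ka_ap * tc$ap_mg_g * 10^(pka_b - ph_iw) / Y +
      (P * tc$f_nl + Pnp * tc$f_np) / Y
  } else {
    Y <- .ionization(pka, ph_p)
    X <- .ionization(pka, ph_iw)
    lip_t <- (P * tc$f_nl + Pnp * tc$f_np) / Y
    lip_p <- (10^drug$logP * pl$f_nl + (0.3 * 10^drug$logP + 0.7) * pl$f_np) / Y
    kpu <- tc$f_ew + X / Y * tc$f_iw + lip_t +
      (tc$ra_alb %||% 0) * max(0, 1 / fu_p - 1 - lip_p)
  }
  unname(kpu * fu_p)
}

# Plasma-protein affinity back-calculated so that the plasma compartment
# reproduces the measured unbound fraction.
.k_protein <- function(logp, fu_p, plasma = .as_composition("plasma")) {
  if (plasma$f_protein <= 0) return(0)
  max(0, (1 / fu_p - plasma$f_water - 10^logp * plasma$f_lipid) /
        plasma$f_protein)
}

#' Tissue-composition standard partition coefficient
#'
#' Lumped water/lipid/protein partitioning: lipid affinity is the octanol
#' partition 10^logP, protein affinity is back-calculated from the unbound
#' plasma fraction, and Kp is the ratio of the tissue to the plasma
#' affinity sums.
#' @inheritParams kp_rodgers_rowland
#' @param plasma plasma composition (override for degenerate media)
#' @return Kp (tissue:plasma)
#' @export
kp_pksim_standard <- function(drug, tissue, fu_p = drug$fu_p,
                              plasma = "plasma") {
  tc <- .as_composition(tissue)
  pl <- .as_composition(plasma)
  K <- 10^drug$logP
  kprot <- .k_protein(drug$logP, fu_p, pl)
  num <- tc$f_water + K * tc$f_lipid + kprot * tc$f_protein
  den <- pl$f_water + K * pl$f_lipid + kprot * pl$f_protein
  unname(num / den)
}

#' Schmitt-type charge-dependent partition coefficient
#'
#' As the standard composition method, but the membrane (lipid) affinity of
#' the ionized species is attenuated to a fixed fraction of the neutral
#' species' affinity, evaluated at the local pH of each phase.
#' @inheritParams kp_rodgers_rowland
#' @param gamma_ion membrane affinity of the ionized relative to the
#'   neutral species (default 0.05)
#' @param plasma plasma composition (override for degenerate media)
#' @return Kp (tissue:plasma)
#' @export
kp_schmitt <- function(drug, tissue, fu_p = drug$fu_p, gamma_ion = 0.05,
                       plasma = "plasma") {
  tc <- .as_composition(tissue)
  pl <- .as_composition(plasma)
  pka <- drug$pka %||% list()
  kmem <- function(ph) {
    fn <- .fraction_neutral(pka, ph)
    10^drug$logP * (fn + (1 - fn) * gamma_ion)
  }
  kprot <- .k_protein(drug$logP, fu_p, pl)
  num <- tc$f_water + kmem(tc$ph_iw %||% 7) * tc$f_lipid +
    kprot * tc$f_protein
  den <- pl$f_water + kmem(7.4) * pl$f_lipid + kprot * pl$f_protein
  unname(num / den)
}

#' Whole-blood to plasma concentration ratio
#'
#' B:P = (1 - Hct) + Hct * K_ery, where the erythrocyte:plasma ratio K_ery
#' follows from the erythrocyte water, lipid and protein content: the
#' unbound erythrocyte partition is water plus 10^logP times the lipid
#' volume fraction plus the plasma-derived protein affinity times the
#' protein volume fraction, multiplied by the unbound plasma fraction.
#'
#' @param drug a `drug_model` or list with `logP`, `fu_p` and optionally
#'   `erythrocyte` (`vf_proteins`, `vf_lipid`)
#' @param hematocrit hematocrit fraction in [0, 1)
#' @param fu_p unbound plasma fraction (defaults to the drug's)
#' @return B:P ratio
#' @export
blood_plasma_ratio <- function(drug, hematocrit, fu_p = drug$fu_p) {
  stopifnot(hematocrit >= 0, hematocrit < 1)
  (1 - hematocrit) + hematocrit * kp_erythrocyte(drug, fu_p)
}

#' Erythrocyte:plasma concentration ratio
#' @inheritParams blood_plasma_ratio
#' @export
kp_erythrocyte <- function(drug, fu_p = drug$fu_p) {
  ery <- drug$erythrocyte %||% list(vf_proteins = 0.06, vf_lipid = 0)
  bc <- .as_composition("rbc")
  kprot <- .k_protein(drug$logP, drug$fu_p)
  kpu <- bc$f_water + 10^drug$logP * ery$vf_lipid + kprot * ery$vf_proteins
  unname(fu_p * kpu)
}

#' Partition coefficients for every model compartment
#' @param drug a `drug_model`
#' @param method "pksim", "rodgers_rowland" or "schmitt" (defaults to the
#'   drug's declared distribution method)
#' @param fu_p unbound plasma fraction (defaults to the drug's)
#' @return named vector of Kp values over `compartment_names(blood = FALSE)`
#' @export
kp_all <- function(drug, method = drug$distribution, fu_p = drug$fu_p) {
  fn <- switch(method,
               pksim = kp_pksim_standard,
               rodgers_rowland = kp_rodgers_rowland,
               schmitt = kp_schmitt,
               stop("unknown distribution method: ", method))
  vapply(compartment_names(blood = FALSE), function(cp) {
    max(fn(drug, cp, fu_p = fu_p), 1e-6)
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
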