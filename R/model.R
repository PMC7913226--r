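# Assembly of the whole-body model for one individual and one drug, and its
# numerical solution. Parameter/state layouts mirror src/pbpk.c.

.MPPGL <- 40 # mg microsomal protein per g liver

.NPAR <- 96
.NEQ <- 46
.P <- list(V = 1, Q = 15, KPB = 29, VART = 43, VVEN = 44, VPOR = 45,
           FU = 46, BP = 47, CLFILT = 48, CLSEC = 49, CLHEP = 50,
           VMAX = 51, KM = 52, CLBILE = 53, BILEGUT = 54, INFRATE = 55,
           INFTEND = 56, KT = 57, VFL = 69, KABS = 81, SOL = 93,
           DISS = 94, D1 = 95, D2 = 96) # 1-based offsets into parms
.Y <- list(ART = 15, VEN = 16, POR = 17, DISS = 18, SOLID = 30,
           RENAL = 42, HEP = 43, BILE = 44, FECAL = 45, ABS = 46)

#' Build the whole-body model for one individual and one drug
#'
#' Assembles organ volumes, blood flows, partition coefficients, binding,
#' clearances (scaled by organ size and age-dependent enzyme maturation)
#' and the gastrointestinal absorption chain into the parameter set of the
#' compiled ODE system. Gut dimensions follow the individual's age-specific
#' reference body size (gastrointestinal anatomy is not part of the
#' malnutrition scaling set), while organ flows, clearances and binding
#' reflect the individual's actual, possibly malnutrition-scaled,
#' physiology. Under a fed state the gastric residence time grows linearly
#' with the meal's caloric content (doubling at 300 kcal) and the prandial
#' solubility applies.
#'
#' @param individual a `physiology` object
#' @param drug a `drug_model`
#' @param route one of "iv_infusion", "oral_solution", "enteral_solution",
#'   "oral_suspension", "oral_solid"
#' @param prandial "fasted", "fed" or "fed_high_fat"
#' @param meal a `meal_model()` (fed states)
#' @param dissolution a `dissolution_law` for solid/suspension routes
#' @param saef_overrides named per-segment surface-enhancement overrides
#'   (defaults to the drug's)
#' @return a `pbpk_model` object
#' @export
build_model <- function(individual, drug, route = "oral_solution",
                        prandial = "fasted", meal = NULL,
                        dissolution = NULL,
                        saef_overrides = drug$saef_overrides) {
  .validate_physiology(individual)
  stopifnot(inherits(drug, "drug_model"))
  route <- match.arg(route, c("iv_infusion", "oral_solution",
                              "enteral_solution", "oral_suspension",
                              "oral_solid"))
  orgs <- compartment_names(blood = FALSE)
  m <- individual$organ_masses

  protein_factor <- .protein_factor_of(individual)
  fu <- scale_fu(drug$fu_p, protein_factor)
  bp <- blood_plasma_ratio(drug, individual$hematocrit, fu)
  kp <- kp_all(drug, fu_p = fu)

  p <- numeric(.NPAR)
  p[.P$V + seq_along(orgs) - 1] <- m[orgs]          # density 1 kg/L
  p[.P$Q + seq_along(orgs) - 1] <-
    individual$specific_perfusion[orgs] * m[orgs]
  p[.P$KPB + seq_along(orgs) - 1] <- kp[orgs] / bp
  p[.P$VART] <- m[["blood_arterial"]] / 1.06        # blood density kg/L
  p[.P$VVEN] <- m[["blood_venous"]] / 1.06
  p[.P$VPOR] <- m[["blood_portal"]] / 1.06
  p[.P$FU] <- fu
  p[.P$BP] <- bp

  # clearances; specific clearances are per organ volume (1/min)
  vkid <- m[["kidney"]]; vliv <- m[["liver"]]
  ont <- individual$ontogeny
  if (!is.null(drug$renal)) {
    p[.P$CLFILT] <- (drug$renal$gfr_fraction %||% 0) * individual$gfr
    p[.P$CLSEC] <- (drug$renal$cl_spec %||% 0) * 60 * vkid *
      ont[["tubular_secretion"]]
  }
  if (!is.null(drug$hepatic)) {
    h <- drug$hepatic
    fo <- ont[[h$pathway %||% "unspecific_hepatic"]]
    if (!is.null(h$vmax)) {
      p[.P$VMAX] <- h$vmax * .MPPGL * (vliv * 1000) * 60 * drug$mw * 1e-9 * fo
      p[.P$KM] <- h$km * drug$mw / 1000
    }
    if (!is.null(h$cl_spec)) p[.P$CLHEP] <- h$cl_spec * 60 * vliv * fo
    if (!is.null(h$cl_int)) {
      p[.P$CLHEP] <- h$cl_int * .MPPGL * (vliv * 1000) * 60 * 1e-6 * fo
    }
  }
  if (!is.null(drug$biliary)) {
    p[.P$CLBILE] <- drug$biliary$cl_spec * 60 * vliv
    p[.P$BILEGUT] <- 1
  }

  # gastrointestinal chain, sized by the age-specific reference body
  gi <- gi_segment_table()
  ref <- reference_individual(individual$age, individual$sex)
  adult_bwt <- reference_individual(30, individual$sex)$bwt
  sc_area <- (ref$bwt / adult_bwt)^0.75
  sc_vol <- ref$bwt / adult_bwt
  transit <- gi$transit_h
  fluid <- gi$fluid_mL * sc_vol
  fed <- prandial %in% c("fed", "fed_high_fat")
  if (fed) {
    kcal <- if (is.null(meal)) 0 else meal$kcal
    transit[1] <- transit[1] * (1 + kcal / 300)
    if (!is.null(meal)) fluid[1] <- fluid[1] + meal$volume_mL
  }
  saef <- gi$saef
  if (!is.null(saef_overrides)) {
    idx <- match(names(saef_overrides), gi$segment)
    saef[idx[!is.na(idx)]] <- unlist(saef_overrides)[!is.na(idx)]
  }
  p_cm_h <- (drug$p_int %||% 0) * 1e-6 * 60
  p[.P$KT + 0:11] <- 1 / transit
  p[.P$VFL + 0:11] <- fluid
  p[.P$KABS + 0:11] <- p_cm_h * gi$area_cm2 * sc_area * saef
  p[.P$SOL] <- if (route == "iv_infusion") 0 else
    drug_solubility(drug, prandial)

  structure(list(parms = p, individual = individual, drug = drug,
                 route = route, prandial = prandial, meal = meal,
                 dissolution = dissolution, fu = fu, bp = bp, kp = kp),
            class = "pbpk_model")
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat(sprintf("<pbpk_model> %s, %s, %s; fu_p %.4g, B:P %.3f\n",
              x$drug$name, x$route, x$prandial, x$fu, x$bp))
  invisible(x)
}

#' Single-dose regimen
#' @param dose_mg dose in mg (flat) -- compute mg/kg doses upstream
#' @param infusion_min infusion duration for intravenous dosing, minutes
#' @return a `regimen` list
#' @export
regimen_single <- function(dose_mg, infusion_min = 5) {
  stopifnot(dose_mg >= 0)
  list(dose_mg = dose_mg, infusion_min = infusion_min)
}

#' Simulate a dosing regimen
#'
#' Solves the model with a stiff-capable integrator and returns venous
#' plasma and whole-blood concentration-time curves together with
#' cumulative elimination by pathway and a mass-balance audit: at every
#' output time the drug administered so far must equal body burden plus
#' lumen content plus cumulative elimination to within 0.1%.
#'
#' @param model a `pbpk_model`
#' @param regimen a `regimen_single()`
#' @param t_grid increasing output times, hours, starting at 0
#' @param solver_opts list with `rtol`, `atol`, `maxsteps`
#' @return a `pk_profile` data.frame with attributes `mass_balance_error`
#'   and `dose_mg`
#' @export
simulate_pk <- function(model, regimen,
                        t_grid = seq(0, 24, by = 0.25),
                        solver_opts = list()) {
  stopifnot(inherits(model, "pbpk_model"), !is.unsorted(t_grid),
            t_grid[1] == 0)
  so <- modifyList(list(rtol = 1e-8, atol = 1e-10, maxsteps = 500000),
                   solver_opts)
  p <- model$parms
  y0 <- numeric(.NEQ)
  dose <- regimen$dose_mg
  inf_tend <- 0

  if (model$route == "iv_infusion") {
    if (regimen$infusion_min > 0) {
      inf_tend <- regimen$infusion_min / 60
      p[.P$INFRATE] <- dose / inf_tend
      p[.P$INFTEND] <- inf_tend
    } else {
      y0[.Y$VEN] <- dose # bolus
    }
  } else if (model$route %in% c("oral_solution", "enteral_solution")) {
    cap <- p[.P$SOL] * p[.P$VFL] # mg soluble in gastric fluid
    y0[.Y$DISS] <- min(dose, cap)
    excess <- dose - y0[.Y$DISS]
    if (excess > 0) { # precipitated fraction redissolves first-order
      y0[.Y$SOLID] <- excess
      law <- weibull_dissolution(0.1, 1)
      p[.P$DISS] <- 1; p[.P$D1] <- law$lambda; p[.P$D2] <- law$shape
    }
  } else if (model$route == "oral_solid") {
    law <- model$dissolution
    if (is.null(law) || law$type != "weibull") {
      stop("oral_solid route needs a Weibull dissolution law")
    }
    y0[.Y$SOLID] <- dose
    p[.P$DISS] <- 1; p[.P$D1] <- law$lambda; p[.P$D2] <- law$shape
  } else if (model$route == "oral_suspension") {
    law <- model$dissolution
    if (is.null(law) || law$type != "particle") {
      stop("oral_suspension route needs a particle dissolution law")
    }
    y0[.Y$SOLID] <- dose
    p[.P$DISS] <- 2; p[.P$D1] <- law$k; p[.P$D2] <- max(dose, 1e-12)^(1 / 3)
  }

  times <- sort(unique(c(t_grid, if (inf_tend > 0) inf_tend)))
  out <- deSolve::ode(y = y0, times = times, func = "pbpk_derivs",
                      parms = p, dllname = "malnpbpk",
                      initfunc = "pbpk_initmod", method = "lsoda",
                      rtol = so$rtol, atol = so$atol, maxsteps = so$maxsteps)
  if (attr(out, "istate")[1] < 0) {
    stop("ODE solver failed for ", model$drug$name,
         " (istate ", attr(out, "istate")[1], ")")
  }
  out <- out[out[, 1] %in% t_grid, , drop = FALSE]
  y <- out[, -1, drop = FALSE]

  vven <- p[.P$VVEN]; bp <- p[.P$BP]
  blood <- pmax(y[, .Y$VEN] / vven, 0)
  given <- if (inf_tend > 0) dose * pmin(out[, 1] / inf_tend, 1) else dose
  body <- rowSums(y[, 1:17, drop = FALSE]) +
    rowSums(y[, .Y$DISS + 0:11, drop = FALSE]) +
    rowSums(y[, .Y$SOLID + 0:11, drop = FALSE])
  elim <- y[, .Y$RENAL] + y[, .Y$HEP] + y[, .Y$FECAL] +
    if (p[.P$BILEGUT] > 0.5) 0 else y[, .Y$BILE]
  mb <- if (dose > 0) max(abs(body + elim - given) / dose) else 0

  res <- data.frame(time_h = out[, 1],
                    plasma_mg_L = blood / bp,
                    blood_mg_L = blood,
                    eliminated_renal_mg = y[, .Y$RENAL],
                    eliminated_hepatic_mg = y[, .Y$HEP],
                    eliminated_biliary_mg = y[, .Y$BILE],
                    eliminated_fecal_mg = y[, .Y$FECAL],
                    absorbed_mg = y[, .Y$ABS])
  attr(res, "mass_balance_error") <- mb
  attr(res, "dose_mg") <- dose
  attr(res, "fu") <- model$fu
  attr(res, "bp") <- bp
  class(res) <- c("pk_profile", "data.frame")
  res
}

#' Output time grid for a study duration
#'
#' Dense sampling over absorption and early disposition, geometric spacing
#' over the terminal phase.
#' @param sim_hours total duration
#' @return numeric vector of times starting at 0
#' @export
default_grid <- function(sim_hours) {
  early <- seq(0, min(2, sim_hours), by = 0.1)
  mid <- seq(2, min(24, sim_hours), by = 0.5)
  late <- if (sim_hours > 24) exp(seq(log(24), log(sim_hours),
                                      length.out = 40)) else NULL
  sort(unique(round(c(early, mid, late), 4)))
}
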