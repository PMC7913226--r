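# Shared fixtures for the test suite; everything is built in code.

ref_man <- function() reference_individual(30, "male")

small_pop <- function(n = 20, ages = c(46 / 12, 48 / 12), seed = 11) {
  generate_population(population_spec(n, ages, 0.5, seed = seed))
}

psps_cached <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- build_psp_table()
    tab
  }
})

# A synthetic neutral probe compound for partition/engine limit cases.
probe_drug <- function(logP = 1, fu_p = 1, pka = list()) {
  validate_drug(list(
    name = "probe", logP = logP, fu_p = fu_p, mw = 200, pka = pka,
    solubility = list(list(mg_mL = 100, ph = 7, prandial = "any")),
    distribution = "pksim", p_int = 100))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}

# Degenerate parameterization collapsing the whole-body system to a single
# well-stirred volume V with first-order clearance CL: organ exchange is
# made effectively instantaneous and all volume lumped into blood, lung and
# liver, so C(t) = (D/V) exp(-CL t / V) analytically after the brief
# mixing transient.
one_compartment_model <- function(V = 10, CL = 2) {
  m <- build_model(ref_man(), probe_drug(), route = "iv_infusion")
  P <- malnpbpk:::.P
  p <- numeric(malnpbpk:::.NPAR)
  p[P$V + 0:13] <- 1e-9
  p[P$KPB + 0:13] <- 1
  p[P$V + 9] <- 0.48 * V   # liver
  p[P$V + 5] <- 0.02 * V   # lung
  p[P$Q + 9] <- 1e7        # near-instant hepatic equilibration
  p[P$VART] <- 0.2 * V
  p[P$VVEN] <- 0.3 * V
  p[P$VPOR] <- 1e-9
  p[P$FU] <- 1; p[P$BP] <- 1
  p[P$CLHEP] <- CL
  p[P$KT + 0:11] <- 1
  p[P$VFL + 0:11] <- 1
  m$parms <- p
  m
}

# Simulate a drug's adult reference-study setup for the reference man.
dev_profile <- function(name, dose = NULL, solver_opts = list()) {
  d <- load_drug(name)
  s <- formulation_for_study(d, "development")
  meal <- if (!is.null(s$meal)) meal_model(s$meal$volume_mL, s$meal$kcal)
  m <- build_model(ref_man(), d, route = s$route,
                   prandial = if (is.null(s$prandial)) "fasted" else s$prandial,
                   meal = meal, dissolution = s$dissolution)
  inf <- if (is.null(s$infusion_min)) 5 else s$infusion_min
  simulate_pk(m, regimen_single(if (is.null(dose)) s$dose_mg else dose, inf),
              t_grid = default_grid(s$sim_hours), solver_opts = solver_opts)
}
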