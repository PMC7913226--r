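#' Deterministic reference individual
#'
#' Builds the reference (typical) body for a given age and sex from the
#' embedded age/sex grid of organ masses, specific perfusion rates,
#' hematology and renal function. Organ masses are interpolated linearly in
#' age between grid points, which preserves mass closure exactly: the body
#' weight of the returned individual is the sum of its compartment masses.
#'
#' @param age age in years, within the supported grid (0.25--80)
#' @param sex "male" or "female"
#' @return an object of class `physiology` with fields `age`, `sex`, `bwt`
#'   (kg), `ht` (cm), `organ_masses` (named, kg), `specific_perfusion`
#'   (named, L/h per kg tissue), `hematocrit`, `albumin` (g/L), `agp` (g/L),
#'   `gfr` (L/h) and `ontogeny` (named fractions of adult activity)
#' @export
reference_individual <- function(age, sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (!is.finite(age) || age < 0.25 || age > 80) {
    stop("unsupported age: ", age, " y (supported grid is 0.25-80 y)")
  }
  phys <- reference_physiology_table()
  scal <- reference_scalars_table()
  phys <- phys[phys$sex == sex, ]
  scal <- scal[scal$sex == sex, ]
  comps <- compartment_names()

  masses <- vapply(comps, function(cp) {
    sub <- phys[phys$compartment == cp, ]
    approx(sub$age_y, sub$mass_kg, xout = age, rule = 2)$y
  }, numeric(1))
  perf <- vapply(comps, function(cp) {
    sub <- phys[phys$compartment == cp, ]
    sub$perfusion_L_h_kg[1]
  }, numeric(1))
  sc <- function(col) approx(scal$age_y, scal[[col]], xout = age, rule = 2)$y

  structure(list(
    age = age, sex = sex,
    bwt = sum(masses),
    ht = sc("ht_cm"),
    organ_masses = masses,
    specific_perfusion = perf,
    hematocrit = sc("hematocrit"),
    albumin = sc("albumin_g_L"),
    agp = sc("agp_g_L"),
    gfr = sc("gfr_L_h"),
    ontogeny = vapply(ontogeny_pathways(), ontogeny_factor, numeric(1),
                      age = age)
  ), class = "physiology")
}

#' @export
print.physiology <- function(x, ...) {
  cat(sprintf("<physiology> %s, %.2f y, BWT %.2f kg, HT %.1f cm\n",
              x$sex, x$age, x$bwt, x$ht))
  cat(sprintf("  hematocrit %.3f, albumin %.1f g/L, GFR %.2f L/h, CO %.1f L/h\n",
              x$hematocrit, x$albumin, x$gfr, cardiac_output(x)))
  invisible(x)
}

#' Cardiac output of an individual
#'
#' The sum of compartment blood flows (specific perfusion times compartment
#' mass) over all perfused organs excluding the lung, which sits in series
#' with the systemic circulation and receives the whole cardiac output.
#' @param individual a `physiology` object
#' @return cardiac output in L/h
#' @export
cardiac_output <- function(individual) {
  m <- individual$organ_masses
  q <- individual$specific_perfusion
  keep <- setdiff(names(m), "lung")
  sum(q[keep] * m[keep])
}

#' Supported clearance-maturation pathways
#' @return character vector of pathway names
#' @export
ontogeny_pathways <- function() {
  c("CYP1A2", "CYP3A4", "unspecific_hepatic", "tubular_secretion")
}

# Hill-type maturation constants: birth fraction, age of half-maturation (y)
# and Hill coefficient. CYP3A4 is anchored to exceed 0.9 by three years of
# age; CYP1A2 has a slower onset but is essentially mature before two years.
.ontogeny_pars <- list(
  CYP1A2             = c(f0 = 0.05, a50 = 0.40, hill = 2.0),
  CYP3A4             = c(f0 = 0.10, a50 = 0.30, hill = 1.0),
  unspecific_hepatic = c(f0 = 0.30, a50 = 0.10, hill = 1.0),
  tubular_secretion  = c(f0 = 0.20, a50 = 0.40, hill = 1.0)
)

#' Maturation of a clearance pathway
#'
#' Fraction of adult activity at a given age, following a sigmoid
#' (Hill-type) maturation curve normalized to reach exactly 1 at adult age.
#' Non-decreasing in age, in (0, 1].
#' @param pathway one of `ontogeny_pathways()`
#' @param age age in years
#' @return fraction of adult activity
#' @export
ontogeny_factor <- function(pathway, age) {
  p <- .ontogeny_pars[[pathway]]
  if (is.null(p)) stop("unknown ontogeny pathway: ", pathway)
  f <- function(a) p[["f0"]] + (1 - p[["f0"]]) *
    a^p[["hill"]] / (a^p[["hill"]] + p[["a50"]]^p[["hill"]])
  unname(pmin(1, f(age) / f(18)))
}

#' Specification of a stochastic virtual population
#'
#' @param n number of individuals (>= 1)
#' @param age_range two ages in years, ordered
#' @param sex_ratio fraction of males in [0, 1]
#' @param seed integer RNG seed; identical specs reproduce identical
#'   populations bit-for-bit
#' @param cv_organ lognormal coefficient of variation applied independently
#'   to each organ mass around its age-specific reference
#' @param sd_size standard deviation (log scale) of the shared body-size
#'   factor that scales all organ masses jointly and correlates body weight
#'   with height
#' @param sd_height residual lognormal variability of height
#' @param cv_scalar lognormal CV for hematocrit, plasma proteins and GFR
#' @return a `population_spec` list
#' @export
population_spec <- function(n, age_range, sex_ratio = 0.5, seed = 1L,
                            cv_organ = 0.15, sd_size = 0.06,
                            sd_height = 0.025, cv_scalar = 0.05) {
  stopifnot(n >= 1, length(age_range) == 2, age_range[1] <= age_range[2],
            sex_ratio >= 0, sex_ratio <= 1)
  structure(list(n = as.integer(n), age_range = as.numeric(age_range),
                 sex_ratio = sex_ratio, seed = as.integer(seed),
                 cv_organ = cv_organ, sd_size = sd_size,
                 sd_height = sd_height, cv_scalar = cv_scalar),
            class = "population_spec")
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a stochastic virtual population
#'
#' Ages are drawn uniformly within the age range and sexes by the sex ratio.
#' Each organ mass is perturbed lognormally around its age-specific
#' reference with an independent CV, jointly multiplied by a shared
#' body-size factor; body weight is recomputed as the sum of the sampled
#' organ masses so that mass closure holds for every individual. Height
#' shares the body-size factor, inducing the body-weight/height correlation
#' of real populations. With all variability parameters at zero every
#' individual equals `reference_individual()` at its sampled age.
#'
#' @param spec a `population_spec`
#' @return list of `physiology` objects of length `spec$n`
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  comps <- compartment_names()
  sdlog <- sqrt(log(1 + spec$cv_organ^2))
  sdsc <- sqrt(log(1 + spec$cv_scalar^2))
  .with_seed(spec$seed, {
    ages <- runif(spec$n, spec$age_range[1], spec$age_range[2])
    sexes <- ifelse(runif(spec$n) < spec$sex_ratio, "male", "female")
    lapply(seq_len(spec$n), function(i) {
      ref <- reference_individual(ages[i], sexes[i])
      z_size <- rnorm(1, 0, spec$sd_size)
      eps <- rnorm(length(comps), 0, sdlog)
      masses <- ref$organ_masses * exp(z_size + eps - 0.5 * sdlog^2)
      ref$organ_masses <- masses
      ref$bwt <- sum(masses)
      ref$ht <- ref$ht * exp(0.35 * z_size + rnorm(1, 0, spec$sd_height))
      ref$hematocrit <- min(0.65, ref$hematocrit * exp(rnorm(1, 0, sdsc)))
      ref$albumin <- ref$albumin * exp(rnorm(1, 0, sdsc))
      ref$agp <- ref$agp * exp(rnorm(1, 0, sdsc))
      ref$gfr <- ref$gfr * exp(rnorm(1, 0, sdsc))
      ref$id <- i
      ref
    })
  })
}

#' Exclude biometric outliers from a population
#'
#' Removes individuals whose body-weight/height ratio (kg/m) deviates more
#' than `k` standard deviations from the population mean. When both sexes
#' are present the mean and SD are computed per sex; with a single sex they
#' are pooled. Input order is retained.
#'
#' @param population list of `physiology` objects (length >= 2)
#' @param k SD multiplier (default 1)
#' @return the filtered population
#' @export
exclude_outliers <- function(population, k = 1) {
  if (length(population) < 2) {
    stop("need at least two individuals to compute an SD")
  }
  ratio <- vapply(population, function(p) p$bwt / (p$ht / 100), numeric(1))
  sexes <- vapply(population, `[[`, character(1), "sex")
  keep <- logical(length(population))
  for (s in unique(sexes)) {
    idx <- which(sexes == s)
    mu <- mean(ratio[idx]); sg <- sd(ratio[idx])
    if (!is.finite(sg) || sg == 0) keep[idx] <- TRUE
    else keep[idx] <- abs(ratio[idx] - mu) <= k * sg
  }
  population[keep]
}

#' Tabulate a population
#'
#' One row per individual with id, age, sex, body weight, height and one
#' column per compartment mass.
#' @param population list of `physiology` objects
#' @return data.frame
#' @export
population_table <- function(population) {
  comps <- compartment_names()
  do.call(rbind, lapply(seq_along(population), function(i) {
    p <- population[[i]]
    cbind(data.frame(id = if (is.null(p$id)) i else p$id, age = p$age,
                     sex = p$sex, bwt = p$bwt, ht = p$ht),
          as.data.frame(as.list(p$organ_masses))[comps])
  }))
}

.validate_physiology <- function(p) {
  stopifnot(inherits(p, "physiology"),
            all(p$organ_masses > 0), all(p$specific_perfusion >= 0),
            p$hematocrit > 0, p$hematocrit < 1,
            p$albumin > 0, p$gfr > 0,
            abs(sum(p$organ_masses) - p$bwt) <= 1e-3 * p$bwt)
  invisible(p)
}
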