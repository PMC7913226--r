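#' Dissolution laws
#'
#' Construct a dissolution law for a solid oral formulation: either a
#' Weibull release profile parameterized by the time to 50% dissolved and a
#' shape factor, or Noyes-Whitney dissolution of monodisperse spherical
#' particles.
#'
#' The Weibull scale is chosen so that exactly half the dose is dissolved
#' at `t50`: scale = t50 / ln(2)^(1/shape).
#'
#' @param t50 time to 50% dissolved, hours (> 0)
#' @param shape Weibull shape factor (> 0)
#' @return a `dissolution_law` object
#' @export
weibull_dissolution <- function(t50, shape) {
  if (t50 <= 0 || shape <= 0) stop("t50 and shape must be positive")
  structure(list(type = "weibull", t50 = t50, shape = shape,
                 lambda = t50 / log(2)^(1 / shape)),
            class = "dissolution_law")
}

#' @rdname weibull_dissolution
#' @param radius_um particle radius, micrometers
#' @param diffusion_cm2_s aqueous diffusion coefficient (default 5e-6)
#' @param density_mg_cm3 particle density (default 1200)
#' @export
particle_dissolution <- function(radius_um, diffusion_cm2_s = 5e-6,
                                 density_mg_cm3 = 1200) {
  if (radius_um <= 0) stop("particle radius must be positive")
  r_cm <- radius_um * 1e-4
  h_cm <- min(r_cm, 30e-4) # diffusion-layer thickness capped at 30 um
  k <- 3 * diffusion_cm2_s * 3600 / (density_mg_cm3 * r_cm * h_cm)
  structure(list(type = "particle", radius_um = radius_um,
                 k = k), # cm^3/(mg h); rate = k * m0^(1/3) m^(2/3) (Cs - C)
            class = "dissolution_law")
}

#' Fraction dissolved under sink conditions
#'
#' Closed-form fraction-of-dose dissolved at time t, ignoring any
#' solubility limitation (the full simulation applies the solubility cap
#' dynamically). For the Weibull law: 1 - exp(-(t/scale)^shape), which
#' equals 0.5 exactly at t50. For particle dissolution the sink-condition
#' cube-root law is integrated.
#'
#' @param t time, hours (>= 0)
#' @param law a `dissolution_law`
#' @param solubility_mg_mL bulk solubility, used only by the particle law's
#'   sink rate
#' @return fraction in [0, 1], non-decreasing in t
#' @export
dissolution_fraction <- function(t, law, solubility_mg_mL = NULL) {
  stopifnot(inherits(law, "dissolution_law"), all(t >= 0))
  if (law$type == "weibull") {
    1 - exp(-(t / law$lambda)^law$shape)
  } else {
    if (is.null(solubility_mg_mL)) {
      stop("particle dissolution needs a solubility")
    }
    # sink: dm/dt = -k m0^(1/3) m^(2/3) Cs, so the relative particle size
    # (m/m0)^(1/3) shrinks linearly at rate k Cs / 3
    u <- pmax(0, 1 - law$k * solubility_mg_mL * t / 3)
    1 - u^3
  }
}
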