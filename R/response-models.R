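#' Rectangular-hyperbola light response
#'
#' Net response `alpha*I*pn_max / (alpha*I + pn_max) - rd`. Strictly
#' increasing in irradiance with asymptote `pn_max - rd`; it has no finite
#' saturation irradiance.
#'
#' @param i Irradiance, umol photons m^-2 s^-1 (vectorised, >= 0).
#' @param p An [rh_params()] object.
#' @return Net response, umol m^-2 s^-1.
#' @examples
#' rh_pn(200, rh_params(0.0659, 35.93, 3.41))
#' @export
rh_pn <- function(i, p) {
  stopifnot(inherits(p, "rh_params"))
  check_irradiance(i)
  p$alpha * i * p$pn_max / (p$alpha * i + p$pn_max) - p$rd
}

#' Non-rectangular-hyperbola light response
#'
#' Smaller root of `theta*P^2 - (alpha*I + pn_max)*P + alpha*I*pn_max = 0`,
#' minus `rd`. Evaluated through the algebraically equivalent quotient form
#' `2*alpha*I*pn_max / (A + sqrt(A^2 - 4*theta*alpha*I*pn_max))` with
#' `A = alpha*I + pn_max`, which is stable as `theta -> 0` (where the family
#' degenerates to the rectangular hyperbola). At `theta = 1` it equals the
#' Blackman limiting response `min(alpha*I, pn_max) - rd` exactly.
#'
#' @inheritParams rh_pn
#' @param p An [nrh_params()] object.
#' @return Net response, umol m^-2 s^-1.
#' @examples
#' nrh_pn(200, nrh_params(0.0522, 33.70, theta = 1, rd = 2.91))
#' @export
nrh_pn <- function(i, p) {
  stopifnot(inherits(p, "nrh_params"))
  check_irradiance(i)
  a <- p$alpha * i
  s <- a + p$pn_max
  disc <- pmax(s^2 - 4 * p$theta * a * p$pn_max, 0)
  gross <- ifelse(i == 0, 0, 2 * a * p$pn_max / (s + sqrt(disc)))
  gross - p$rd
}

#' Mechanistic light-response family with photoinhibition
#'
#' Evaluates `alpha * (1 - beta*I) / (1 + gamma*I) * I - offset`. With
#' `beta > 0` the curve rises to a single interior maximum at the
#' saturation irradiance ([ye_sat_irradiance()]) and declines beyond it
#' (photoinhibition / PSII down-regulation); with `beta = 0` it saturates
#' monotonically towards the asymptote `alpha/gamma - offset`.
#'
#' @inheritParams rh_pn
#' @param p A [ye_params()] object.
#' @return Response value (net CO2 assimilation when `offset` is the dark
#'   respiration; electron transport rate when `offset = 0`).
#' @examples
#' p <- invert_ye(0.3424, 184.10, 1699.64)
#' ye_response(1699.64, p)
#' @export
ye_response <- function(i, p) {
  stopifnot(inherits(p, "ye_params"))
  check_irradiance(i)
  p$alpha * (1 - p$beta * i) / (1 + p$gamma * i) * i - p$offset
}

#' Quantum efficiency of the mechanistic family
#'
#' The derivative of the mechanistic light response with respect to
#' irradiance: `alpha * (1 - 2*beta*I - beta*gamma*I^2) / (1 + gamma*I)^2`.
#' It equals `alpha` at `I = 0`, is zero exactly at the saturation
#' irradiance, and is negative beyond it (supersaturating light lowers the
#' net response).
#'
#' @inheritParams ye_response
#' @return Quantum efficiency, umol umol^-1 photons.
#' @export
ye_quantum_efficiency <- function(i, p) {
  stopifnot(inherits(p, "ye_params"))
  check_irradiance(i)
  p$alpha * (1 - 2 * p$beta * i - p$beta * p$gamma * i^2) / (1 + p$gamma * i)^2
}

#' Maximum response and saturation irradiance of the mechanistic family
#'
#' Closed forms for the interior maximum and its location:
#' `max = alpha * ((sqrt(beta + gamma) - sqrt(beta)) / gamma)^2 - offset`
#' and `I_sat = (sqrt((beta + gamma)/beta) - 1) / gamma`. Both require
#' `beta > 0`; with `beta = 0` the curve has no finite interior maximum
#' (it approaches the asymptote `alpha/gamma - offset`) and no finite
#' saturation irradiance, and a condition of class
#' `"lrc_no_saturation"` is signalled — the same behaviour the hyperbolic
#' families show for every parameter set.
#'
#' @inheritParams ye_response
#' @return `ye_max()`: the maximum response; `ye_sat_irradiance()`: the
#'   saturation irradiance, umol photons m^-2 s^-1.
#' @examples
#' p <- invert_ye(0.3424, 184.10, 1699.64)
#' ye_max(p)
#' ye_sat_irradiance(p)
#' @export
ye_max <- function(p) {
  stopifnot(inherits(p, "ye_params"))
  if (p$beta <= 0) {
    stop(no_saturation_cnd(sprintf(
      "no finite interior maximum for beta = 0; asymptote is alpha/gamma - offset = %g",
      p$alpha / p$gamma - p$offset)))
  }
  p$alpha * ((sqrt(p$beta + p$gamma) - sqrt(p$beta)) / p$gamma)^2 - p$offset
}

#' @rdname ye_max
#' @export
ye_sat_irradiance <- function(p) {
  stopifnot(inherits(p, "ye_params"))
  if (p$beta <= 0) {
    stop(no_saturation_cnd(
      "no finite saturation irradiance for beta = 0 (monotone saturating curve)"))
  }
  (sqrt((p$beta + p$gamma) / p$beta) - 1) / p$gamma
}

no_saturation_cnd <- function(msg) {
  structure(class = c("lrc_no_saturation", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Invert maximum and saturation irradiance to mechanistic coefficients
#'
#' Recovers `(beta, gamma)` of the mechanistic family from the initial
#' slope, the maximum response and the saturation irradiance, by exact
#' algebraic inversion of the closed forms in [ye_max()] and
#' [ye_sat_irradiance()]:
#' `beta = (max_value + offset) / (alpha * sat^2)` and
#' `gamma = (1/beta - 2*sat) / sat^2`.
#' The trait triple is feasible only when `beta < 1/sat` (the curve must
#' still be positive at its maximum) and `1/beta > 2*sat` (so that
#' `gamma > 0`); an infeasible combination raises an error naming the
#' violated inequality.
#'
#' @param alpha Initial slope (> 0).
#' @param max_value Maximum net response.
#' @param sat_irradiance Saturation irradiance (> 0).
#' @param offset Offset (dark respiration) used when the maximum is a net
#'   value; default 0.
#' @return A [ye_params()] object that round-trips: `ye_max()` and
#'   `ye_sat_irradiance()` applied to it return `max_value` and
#'   `sat_irradiance`.
#' @examples
#' invert_ye(0.0528, 24.64, 2520.41, offset = 3.46)
#' @export
invert_ye <- function(alpha, max_value, sat_irradiance, offset = 0) {
  check_scalar(alpha, "alpha", positive = TRUE)
  check_scalar(max_value, "max_value")
  check_scalar(sat_irradiance, "sat_irradiance", positive = TRUE)
  check_scalar(offset, "offset", nonnegative = TRUE)
  gross_max <- max_value + offset
  if (gross_max <= 0) {
    stop("infeasible traits: max_value + offset must be > 0", call. = FALSE)
  }
  beta <- gross_max / (alpha * sat_irradiance^2)
  if (beta >= 1 / sat_irradiance) {
    stop("infeasible traits: beta = (max_value + offset)/(alpha*sat^2) = ",
         signif(beta, 6), " violates beta < 1/sat_irradiance = ",
         signif(1 / sat_irradiance, 6),
         " (maximum too high for this slope and saturation irradiance)",
         call. = FALSE)
  }
  if (1 / beta <= 2 * sat_irradiance) {
    stop("infeasible traits: 1/beta = ", signif(1 / beta, 6),
         " violates 1/beta > 2*sat_irradiance = ",
         signif(2 * sat_irradiance, 6), " (gamma would be <= 0)",
         call. = FALSE)
  }
  gamma <- (1 / beta - 2 * sat_irradiance) / sat_irradiance^2
  ye_params(alpha = alpha, beta = beta, gamma = gamma, offset = offset)
}

#' Light compensation point
#'
#' Smallest positive irradiance at which the net response crosses zero.
#' For the rectangular hyperbola the closed form
#' `I_c = rd * pn_max / (alpha * (pn_max - rd))` is used; for the other
#' families the root is bracketed and solved numerically to 1e-8 absolute
#' tolerance on irradiance. `rd = 0` gives `I_c = 0`. If the net response
#' never becomes positive below its maximum, an error of class
#' `"lrc_no_compensation"` is raised.
#'
#' @param p An `lrc_params` object.
#' @param ... Unused.
#' @return The compensation irradiance, umol photons m^-2 s^-1.
#' @examples
#' light_compensation(rh_params(0.0659, 35.93, 3.41))
#' @export
light_compensation <- function(p, ...) UseMethod("light_compensation")

#' @export
light_compensation.rh_params <- function(p, ...) {
  if (p$rd == 0) return(0)
  if (p$pn_max <= p$rd) {
    stop(no_compensation_cnd(
      "net response never reaches zero: asymptote pn_max - rd is not positive"))
  }
  p$rd * p$pn_max / (p$alpha * (p$pn_max - p$rd))
}

#' @export
light_compensation.nrh_params <- function(p, ...) {
  if (p$rd == 0) return(0)
  # monotone family: bracket upper end where the curve is near its asymptote
  upper <- (p$pn_max / p$alpha) * 1e3
  find_zero_crossing(function(i) nrh_pn(i, p), upper)
}

#' @export
light_compensation.ye_params <- function(p, ...) {
  if (p$offset == 0) return(0)
  upper <- if (p$beta > 0) ye_sat_irradiance(p) else 1 / p$gamma * 1e3
  find_zero_crossing(function(i) ye_response(i, p), upper)
}

find_zero_crossing <- function(f, upper) {
  if (f(upper) <= 0) {
    stop(no_compensation_cnd(
      "net response has no zero crossing below its maximum (no compensation point)"))
  }
  stats::uniroot(f, lower = 0, upper = upper, tol = 1e-8)$root
}

no_compensation_cnd <- function(msg) {
  structure(class = c("lrc_no_compensation", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Apparent electron requirement for CO2 assimilation
#'
#' Ratio of the maximum electron transport rate to the maximum net
#' photosynthetic rate, `n_a = j_max / pn_max`: the apparent number of
#' electrons needed to assimilate one CO2 molecule.
#'
#' @param j_max Maximum electron transport rate, umol m^-2 s^-1 (> 0
#'   expected but only `pn_max` is constrained).
#' @param pn_max Maximum net photosynthetic rate, umol m^-2 s^-1; must
#'   be > 0.
#' @return Dimensionless ratio.
#' @examples
#' apparent_electron_requirement(184.10, 24.64)
#' @export
apparent_electron_requirement <- function(j_max, pn_max) {
  if (!is.numeric(pn_max) || any(!is.finite(pn_max)) || any(pn_max <= 0)) {
    stop("`pn_max` must be > 0", call. = FALSE)
  }
  j_max / pn_max
}

#' Closed-form traits of a fitted parameter set
#'
#' Returns the derived traits a parameter set implies: the maximum response
#' (`pn_max`; for the hyperbolic families this is the asymptotic parameter,
#' since they have no interior maximum), the saturation irradiance
#' (`i_sat`; `NA` for the hyperbolic families, which have none), and the
#' light compensation point (`i_c`; `NA` when there is no crossing or no
#' offset channel).
#'
#' @param p An `lrc_params` object.
#' @return A named list with `pn_max`, `i_sat`, `i_c`.
#' @export
derived_traits <- function(p) {
  stopifnot(inherits(p, "lrc_params"))
  ic <- tryCatch(light_compensation(p), lrc_no_compensation = function(e) NA_real_)
  if (inherits(p, "ye_params")) {
    if (p$beta > 0) {
      list(pn_max = ye_max(p), i_sat = ye_sat_irradiance(p), i_c = ic)
    } else {
      list(pn_max = p$alpha / p$gamma - p$offset, i_sat = NA_real_, i_c = ic)
    }
  } else {
    list(pn_max = p$pn_max, i_sat = NA_real_, i_c = ic)
  }
}
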