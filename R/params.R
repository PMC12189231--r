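#' Parameter sets for light-response model families
#'
#' Validated constructors for the three light-response families handled by
#' the package. Irradiance is always in umol photons m^-2 s^-1 and rates in
#' umol m^-2 s^-1 (CO2 for assimilation channels, electrons for the electron
#' transport channel).
#'
#' * `rh_params()` — rectangular hyperbola: initial slope `alpha`
#'   (umol umol^-1 photons), asymptotic maximum `pn_max` and dark
#'   respiration `rd`.
#' * `nrh_params()` — non-rectangular hyperbola: adds the convexity
#'   `theta` in (0, 1]; `theta = 1` is the Blackman limit and
#'   `theta -> 0` recovers the rectangular hyperbola.
#' * `ye_params()` — mechanistic rational-function family
#'   `alpha * (1 - beta*I) / (1 + gamma*I) * I - offset`, where `beta`
#'   (m^2 s umol^-1 photons) is the photoinhibition/down-regulation
#'   coefficient, `gamma` (same units) the saturation coefficient and
#'   `offset` the dark respiration for the net assimilation channel
#'   (0 for electron transport and other channels).
#'
#' @param alpha Initial slope of the light-response curve; must be > 0.
#' @param pn_max Asymptotic maximum of the hyperbolic families; must be > 0.
#' @param rd Dark respiration rate; must be >= 0.
#' @param theta Convexity of the non-rectangular hyperbola, in (0, 1].
#' @param beta Photoinhibition coefficient; must be >= 0.
#' @param gamma Saturation coefficient; must be > 0.
#' @param offset Constant subtracted from the gross response (dark
#'   respiration for the net CO2 channel); must be >= 0.
#'
#' @return An object of class `"rh_params"`, `"nrh_params"` or
#'   `"ye_params"` (all also `"lrc_params"`): a named list of the
#'   validated parameters.
#' @examples
#' rh_params(alpha = 0.0659, pn_max = 35.93, rd = 3.41)
#' ye_params(alpha = 0.0528, beta = 8.38e-5, gamma = 1.09e-3, offset = 3.46)
#' @name lrc_params
NULL

#' @rdname lrc_params
#' @export
rh_params <- function(alpha, pn_max, rd = 0) {
  check_scalar(alpha, "alpha", positive = TRUE)
  check_scalar(pn_max, "pn_max", positive = TRUE)
  check_scalar(rd, "rd", nonnegative = TRUE)
  structure(list(alpha = alpha, pn_max = pn_max, rd = rd),
            class = c("rh_params", "lrc_params"))
}

#' @rdname lrc_params
#' @export
nrh_params <- function(alpha, pn_max, theta, rd = 0) {
  check_scalar(alpha, "alpha", positive = TRUE)
  check_scalar(pn_max, "pn_max", positive = TRUE)
  check_scalar(theta, "theta")
  if (theta <= 0 || theta > 1) {
    stop("`theta` must lie in (0, 1]; got ", format(theta), call. = FALSE)
  }
  check_scalar(rd, "rd", nonnegative = TRUE)
  structure(list(alpha = alpha, pn_max = pn_max, theta = theta, rd = rd),
            class = c("nrh_params", "lrc_params"))
}

#' @rdname lrc_params
#' @export
ye_params <- function(alpha, beta, gamma, offset = 0) {
  check_scalar(alpha, "alpha", positive = TRUE)
  check_scalar(beta, "beta", nonnegative = TRUE)
  check_scalar(gamma, "gamma", positive = TRUE)
  check_scalar(offset, "offset", nonnegative = TRUE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, offset = offset),
            class = c("ye_params", "lrc_params"))
}

#' @export
print.lrc_params <- function(x, ...) {
  fam <- switch(class(x)[1],
                rh_params = "rectangular hyperbola",
                nrh_params = "non-rectangular hyperbola",
                ye_params = "mechanistic (photoinhibition) family")
  cat("Light-response parameters:", fam, "\n")
  vals <- unlist(x)
  cat(paste0("  ", names(vals), " = ", signif(vals, 6), collapse = "\n"), "\n")
  invisible(x)
}

check_scalar <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop("`", name, "` must be a finite numeric scalar", call. = FALSE)
  }
  if (positive && x <= 0) {
    stop("`", name, "` must be > 0; got ", format(x), call. = FALSE)
  }
  if (nonnegative && x < 0) {
    stop("`", name, "` must be >= 0; got ", format(x), call. = FALSE)
  }
  invisible(x)
}

check_irradiance <- function(i) {
  if (!is.numeric(i) || any(!is.finite(i)) || any(i < 0)) {
    stop("irradiance `i` must be finite and >= 0", call. = FALSE)
  }
  invisible(i)
}
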