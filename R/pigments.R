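AVOGADRO <- 6.022e23

#' Light-harvesting pigment pool size from chlorophyll content
#'
#' Converts areal chlorophyll content into the number of light-harvesting
#' pigment molecules in the measured leaf area:
#' `N_0 = chl * 1e-3 / molar_mass * Avogadro * s`. The default molar mass,
#' 900.5 g mol^-1, is the mean of chlorophyll a (893.5) and b (907.5); the
#' default area is the 2 cm^2 window of a leaf-chamber fluorometer. Both
#' are configurable.
#'
#' @param chl Chlorophyll content, mg m^-2 (> 0).
#' @param s Measured leaf area, m^2 (> 0).
#' @param molar_mass Mean chlorophyll molar mass, g mol^-1.
#' @return Number of pigment molecules in the measured area.
#' @examples
#' n0_from_chlorophyll(707.34) # ~9.46e16 molecules in 2 cm^2
#' @export
n0_from_chlorophyll <- function(chl, s = 2e-4, molar_mass = 900.5) {
  check_scalar(chl, "chl", positive = TRUE)
  check_scalar(s, "s", positive = TRUE)
  check_scalar(molar_mass, "molar_mass", positive = TRUE)
  chl * 1e-3 / molar_mass * AVOGADRO * s
}

#' Effective absorption cross-section under actinic light
#'
#' The effective absorption cross-section of a light-harvesting pigment
#' molecule declines from its intrinsic (eigen) value as PSII antennae are
#' down-regulated under light, following the same down-regulation kernel
#' as the electron transport light response:
#' `sigma_eff(I) = sigma_ik * (1 - beta_e*I) / (1 + gamma_e*I)`,
#' with `(beta_e, gamma_e)` taken from the fitted electron transport
#' (J-I) curve. It equals `sigma_ik` in darkness and decreases strictly
#' with irradiance. Beyond `I = 1/beta_e` the antenna is reported as fully
#' down-regulated (0, with a warning).
#'
#' @param sigma_ik Intrinsic absorption cross-section, m^2 (> 0).
#' @param j_params A [ye_params()] object fitted to the electron transport
#'   channel (its `beta`/`gamma` are used; `offset` is ignored).
#' @param i Irradiance, umol photons m^-2 s^-1 (vectorised).
#' @return Effective cross-section, m^2.
#' @examples
#' jp <- invert_ye(0.3424, 184.10, 1699.64)
#' effective_cross_section(1.91e-21, jp, 2000) # ~0.5e-21 m^2
#' @export
effective_cross_section <- function(sigma_ik, j_params, i) {
  check_scalar(sigma_ik, "sigma_ik", positive = TRUE)
  stopifnot(inherits(j_params, "ye_params"))
  check_irradiance(i)
  kernel <- (1 - j_params$beta * i) / (1 + j_params$gamma * i)
  if (any(kernel < 0)) {
    warning("beta_e * i >= 1: antenna reported as fully down-regulated (0)",
            call. = FALSE)
    kernel <- pmax(kernel, 0)
  }
  sigma_ik * kernel
}

#' Excited-state pigment pool under steady illumination
#'
#' Steady-state two-level pumping with ground-state depletion: with photon
#' flux `Phi(I) = I * 1e-6 * Avogadro` photons m^-2 s^-1, the excitation
#' saturation parameter is `x = sigma_ik * Phi(I) * tau` and the number of
#' pigment molecules in the lowest excited state is
#' `N_k = n0 * x / (1 + x)` — zero in darkness, strictly increasing in
#' irradiance and saturating below the total pool `n0`.
#'
#' @param n0 Total pigment molecules (> 0).
#' @param sigma_ik Absorption cross-section, m^2 (> 0).
#' @param tau Mean lowest-excited-state lifetime, s (> 0).
#' @param i Irradiance, umol photons m^-2 s^-1 (vectorised).
#' @return Number of excited-state pigment molecules.
#' @examples
#' excited_state_pool(9.46e16, 1.91e-21, 11.53e-3, 2000)
#' @export
excited_state_pool <- function(n0, sigma_ik, tau, i) {
  check_scalar(n0, "n0", positive = TRUE)
  check_scalar(sigma_ik, "sigma_ik", positive = TRUE)
  check_scalar(tau, "tau", positive = TRUE)
  check_irradiance(i)
  x <- sigma_ik * (i * 1e-6 * AVOGADRO) * tau
  n0 * x / (1 + x)
}

#' Intrinsic cross-section from the electron transport initial slope
#'
#' The initial slope of the electron transport light response aggregates
#' the microscopic constants as
#' `alpha_e = (alpha' * beta' * phi) * sigma_ik * n0_per_area`, where
#' `alpha'` is the PSII/PSI energy distribution coefficient, `beta'` the
#' leaf absorption coefficient and `phi` the exciton utilisation
#' efficiency. These three are not separately identifiable from a single
#' curve, so their product is exposed as one configurable constant
#' `k_product`, and `sigma_ik = alpha_e / (k_product * n0_per_area)`. The
#' default `k_product = 0.379` is a calibration constant, not a derived
#' value.
#'
#' @param alpha_e Initial slope of the J-I curve, umol umol^-1 photons
#'   (> 0).
#' @param n0_per_area Pigment molecules per leaf area, m^-2 (> 0).
#' @param k_product Bundled product `alpha' * beta' * phi` (> 0).
#' @return Intrinsic absorption cross-section, m^2.
#' @examples
#' sigma_ik_from_alpha_e(0.3424, 9.46e16 / 2e-4) # ~1.91e-21 m^2
#' @export
sigma_ik_from_alpha_e <- function(alpha_e, n0_per_area, k_product = 0.379) {
  check_scalar(alpha_e, "alpha_e", positive = TRUE)
  check_scalar(n0_per_area, "n0_per_area", positive = TRUE)
  check_scalar(k_product, "k_product", positive = TRUE)
  alpha_e / (k_product * n0_per_area)
}

#' Pigment photophysics traits from a fitted electron transport curve
#'
#' Bundles the pigment-level derivations: the pigment pool from
#' chlorophyll content ([n0_from_chlorophyll()]), the intrinsic
#' cross-section from the fitted J-I initial slope
#' ([sigma_ik_from_alpha_e()]), and irradiance profiles of the effective
#' cross-section ([effective_cross_section()]) and the excited-state pool
#' ([excited_state_pool()]). The excited-state lifetime is an input
#' (default 11.53 ms): its extraction from fluorescence kinetics is
#' outside the scope of a light-curve experiment.
#'
#' @param j_params A [ye_params()] object for the electron transport
#'   channel, or an `lrc_fit` of that channel (its mean parameters are
#'   used).
#' @param chl Chlorophyll content, mg m^-2.
#' @param s Measured leaf area, m^2.
#' @param tau Mean lowest-excited-state lifetime, s.
#' @param k_product Bundled optical constant, see
#'   [sigma_ik_from_alpha_e()].
#' @param molar_mass Mean chlorophyll molar mass, g mol^-1.
#' @param i_grid Irradiances at which to tabulate the profiles.
#' @return Class `"lrc_pigment_traits"`: list with scalars `n0`,
#'   `n0_per_area`, `sigma_ik`, `tau`, the inputs, and `profiles`, a
#'   data.frame of `i`, `sigma_eff`, `n_k`.
#' @examples
#' jp <- invert_ye(0.3424, 184.10, 1699.64)
#' pigment_traits(jp, chl = 707.34)
#' @export
pigment_traits <- function(j_params, chl, s = 2e-4, tau = 11.53e-3,
                           k_product = 0.379, molar_mass = 900.5,
                           i_grid = default_light_protocol()) {
  if (inherits(j_params, "lrc_fit")) j_params <- j_params$params
  stopifnot(inherits(j_params, "ye_params"))
  n0 <- n0_from_chlorophyll(chl, s, molar_mass)
  n0_per_area <- n0 / s
  sigma_ik <- sigma_ik_from_alpha_e(j_params$alpha, n0_per_area, k_product)
  i_grid <- sort(unique(i_grid))
  profiles <- data.frame(
    i = i_grid,
    sigma_eff = effective_cross_section(sigma_ik, j_params, i_grid),
    n_k = excited_state_pool(n0, sigma_ik, tau, i_grid))
  structure(list(n0 = n0, n0_per_area = n0_per_area, sigma_ik = sigma_ik,
                 tau = tau, chl = chl, s = s, k_product = k_product,
                 molar_mass = molar_mass, j_params = j_params,
                 profiles = profiles),
            class = "lrc_pigment_traits")
}

#' @export
print.lrc_pigment_traits <- function(x, ...) {
  cat("Light-harvesting pigment traits:\n")
  cat(sprintf("  N_0      = %.3g molecules (%.4g mg m^-2 chlorophyll over %.3g m^2)\n",
              x$n0, x$chl, x$s))
  cat(sprintf("  sigma_ik = %.3g m^2\n", x$sigma_ik))
  cat(sprintf("  tau      = %.3g s\n", x$tau))
  hi <- x$profiles[nrow(x$profiles), ]
  cat(sprintf("  at I = %g: sigma_eff = %.3g m^2 (%.1f%% of sigma_ik), N_k = %.3g\n",
              hi$i, hi$sigma_eff, 100 * hi$sigma_eff / x$sigma_ik, hi$n_k))
  invisible(x)
}
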