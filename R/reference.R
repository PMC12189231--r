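#' Reference light-response traits for water hyacinth
#'
#' Published trait values for *Pontederia crassipes* (water hyacinth) from
#' a combined gas-exchange and chlorophyll-fluorescence light-curve study
#' (means over n = 4 replicates). They serve three purposes in the
#' package: defaults for the synthetic-data generator, inputs for worked
#' examples (the closed-form inversion [invert_ye()] turns the fitted
#' traits into mechanistic coefficients), and the measured column for
#' fitted-vs-measured comparisons.
#'
#' Structure: `pn` and `j` hold the mechanistic-family fitted traits of
#' the net assimilation and electron transport channels; `rh` and `nrh`
#' the hyperbolic-family fits of the same data; `measured` the model-free
#' estimates; `pigment` the chlorophyll content, intrinsic cross-section,
#' minimum excited-state lifetime and pigment pool; `efficiency` the
#' fitted and measured maxima/saturation irradiances of the derived
#' efficiency channels.
#'
#' @return A nested list of numeric trait values (units as in the package
#'   conventions: rates umol m^-2 s^-1, irradiance umol photons m^-2
#'   s^-1, cross-sections m^2).
#' @examples
#' tr <- reference_traits()
#' invert_ye(tr$j$alpha, tr$j$j_max, tr$j$i_sat)
#' @export
reference_traits <- function() {
  list(
    pn = list(alpha = 0.0528, pn_max = 24.64, i_sat = 2520.41,
              i_c = 54.17, rd = 3.46, n_a = 7.46),
    j = list(alpha = 0.3424, j_max = 184.10, i_sat = 1699.64),
    rh = list(alpha = 0.0659, pn_max = 35.93, rd = 3.41, i_c = 58.78,
              alpha_e = 0.4658, j_max = 232.08, n_a = 6.45),
    nrh = list(alpha = 0.0522, pn_max = 33.70, rd = 2.91, i_c = 60.02,
               alpha_e = 0.2779, j_max = 188.85, n_a = 5.62),
    measured = list(pn_max = 24.70, i_sat = 2200.00, i_c = 53.06,
                    rd = 3.46, j_max = 186.07, i_e_sat = 1750.00,
                    n_a = 7.52),
    pigment = list(chl = 707.34, sigma_ik = 1.91e-21, tau_min = 11.53e-3,
                   n0 = 9.46e16, s = 2e-4),
    efficiency = list(
      npq = list(max_fitted = 1.366, i_sat_fitted = 2278.76,
                 max_measured = 1.375, i_sat_measured = 2350.00),
      phipsii = list(max_fitted = 0.743, max_measured = 0.762),
      lue = list(max_fitted = 0.027, i_sat_fitted = 384.65,
                 max_measured = 0.030, i_sat_measured = 250.00),
      ce = list(max_fitted = 0.084, i_sat_fitted = 2242.99,
                max_measured = 0.085, i_sat_measured = 2000.00),
      wue_i = list(max_fitted = 44.17, i_sat_fitted = 1621.82,
                   max_measured = 45.91, i_sat_measured = 1500.00),
      wue_inst = list(max_fitted = 1.88, i_sat_fitted = 1391.42,
                      max_measured = 1.96, i_sat_measured = 1300.00))
  )
}

#' Cross-species photosynthetic capacity reference table
#'
#' Static reference table of maximum net photosynthetic rate, saturation
#' irradiance, maximum electron transport rate and its saturation
#' irradiance reported for aquatic macrophytes and C3/C4 crops, for
#' context when comparing fitted traits across species. Ranges are given
#' as `min`/`max` columns; `NA` marks values not reported.
#'
#' @return A data.frame with columns `species`, `pn_max_min`,
#'   `pn_max_max`, `i_sat_min`, `i_sat_max`, `j_max`, `i_e_sat`.
#' @export
cross_species_reference <- function() {
  data.frame(
    species = c("Pontederia crassipes", "Pontederia crassipes",
                "Pontederia crassipes (this package's reference dataset)",
                "Nymphoides peltata", "Nelumbo nucifera",
                "Phragmites australis", "Oryza sativa",
                "Oryza sativa (Kitaake)", "Tamarix ramosissima",
                "Solanum lycopersicum", "Malus pumila", "Glycine max",
                "Zea mays (Nongda 108)", "Sorghum bicolor (KFJT-4)",
                "Sorghum bicolor (KFJT-1)"),
    pn_max_min = c(23.1, 34.5, 24.70, 12.66, 7.1, 9.0, 17.51, 19.56,
                   17.2, 6.34, 15.25, 19.73, 30.36, 37.49, NA),
    pn_max_max = c(30.8, 34.5, 24.70, 12.66, 9.2, 19.5, 27.89, 19.56,
                   24.4, 17.82, 20.29, 19.73, 30.36, 37.49, NA),
    i_sat_min = c(NA, 2358, 2200.0, 219.98, NA, 924.1, 2000, 1641,
                  957, NA, 1413.8, 1800, 2550, 1866.7, NA),
    i_sat_max = c(NA, 2358, 2200.0, 219.98, NA, 2186.3, 2000, 1641,
                  1360, NA, 1874.9, 1800, 2550, 1866.7, NA),
    j_max = c(NA, NA, 186.1, NA, NA, NA, NA, NA, NA, NA, NA, 143.51,
              NA, 170.15, 133.84),
    i_e_sat = c(NA, NA, 1750.0, NA, NA, NA, NA, NA, NA, NA, NA, 1601.6,
                NA, 1640.0, 1600.0))
}
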