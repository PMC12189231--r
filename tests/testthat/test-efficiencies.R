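test_that("efficiency channels are row-wise ratios with tracked units", {
  d <- light_response_dataset(data.frame(
    i = c(0, 100, 400, 800, 1600, 2400),
    pn = c(-3.46, 2, 10, 18, 24.7, 24),
    ci = c(400, 360, 340, 330, 316.5, 320),
    gs = c(0.15, 0.3, 0.45, 0.5, 0.538, 0.55),
    tr = c(3.5, 7, 10.5, 11.7, 12.6, 12.9)))
  d <- derive_channels(d)
  r <- d$data[d$data$i == 1600, ]
  # division oracles; magnitudes match published efficiency maxima
  expect_equal(r$wue_i, 24.7 / 0.538, tolerance = 1e-12)
  expect_equal(r$wue_i, 45.91, tolerance = 1e-3)
  expect_equal(r$wue_inst, 24.7 / 12.6, tolerance = 1e-12)
  expect_equal(r$wue_inst, 1.96, tolerance = 1e-2)
  expect_equal(r$ce, 24.7 / 316.5, tolerance = 1e-12)
  expect_equal(r$lue, 24.7 / 1600, tolerance = 1e-12)
  # LUE undefined in darkness
  expect_true(is.na(d$data$lue[d$data$i == 0]))
  # zero net assimilation gives zero efficiencies
  z <- derive_channels(light_response_dataset(data.frame(
    i = c(0, 50, 100, 200, 400), pn = c(0, 0, 0, 0, 0),
    ci = rep(350, 5), gs = rep(0.3, 5), tr = rep(7, 5))))
  expect_true(all(z$data$wue_i == 0))
  expect_true(all(z$data$ce == 0))
})

test_that("missing or zero denominators flag rather than crash", {
  d <- light_response_dataset(data.frame(
    i = c(0, 100, 400, 800, 1600), pn = c(-3, 2, 10, 18, 24),
    gs = c(0.2, 0, 0.4, 0.5, 0.54)))
  # expects three flags: missing ci and tr columns, plus the zero gs row
  warns <- capture_warnings(out <- derive_channels(d))
  expect_length(warns, 3)
  expect_match(warns, "not derived|NA efficiency", all = TRUE)
  expect_true(is.na(out$data$wue_i[out$data$i == 100]))    # gs == 0 row
  expect_false("ce" %in% names(out$data))
})

test_that("quenching fit recovers generating maximum and saturation", {
  cfg <- simulation_config(seed = 17, jitter_cv = 0,
                           noise_sd = c(npq = 0.02))
  d <- simulate_dataset(cfg)
  fit <- fit_efficiency(d, "npq")
  expect_true(fit$converged)
  expect_lt(rel_err(fit$mean[["max"]], ye_max(cfg$npq_params)), 0.02)
  expect_lt(rel_err(fit$mean[["i_sat"]], ye_sat_irradiance(cfg$npq_params)),
            0.02)
  # fitted maximum agrees with the numeric argmax of the fitted curve
  p1 <- fit$per_replicate[1, ]
  curve <- function(i) p1$alpha * (1 - p1$beta * i) / (1 + p1$gamma * i) * i
  expect_lt(rel_err(p1$max, max(curve(seq(0, 4000, by = 0.5)))), 0.005)
})

test_that("a quenching curve without down-regulation has no finite saturation", {
  p <- ye_params(0.0015, 0, 2.2e-4)
  d <- simulate_curve(p, channel = "npq", noise_sd = 0)
  fit <- fit_efficiency(d, "npq")
  expect_true(is.na(fit$mean[["i_sat"]]))
  # monotone saturating: maximum reported at the asymptote
  expect_equal(fit$mean[["max"]], 0.0015 / 2.2e-4, tolerance = 1e-3)
})

test_that("PSII efficiency fit returns the dark value as its maximum", {
  cfg <- simulation_config(seed = 23, jitter_cv = 0)
  d <- simulate_dataset(cfg)
  fit <- fit_efficiency(d, "phipsii")
  # truth: alpha_e / (0.5 * absorptance)
  phi_dark <- cfg$j_params$alpha / (0.5 * cfg$absorptance)
  expect_lt(rel_err(fit$mean[["max"]], phi_dark), 0.05)
  expect_true(is.na(fit$mean[["i_sat"]]))
  # fitted curve is monotonically decreasing
  p1 <- fit$per_replicate[1, ]
  curve <- p1$alpha * (1 - p1$beta * (0:2400)) / (1 + p1$gamma * (0:2400))
  expect_true(all(diff(curve) < 0))
})

test_that("water-use and carboxylation channels fit with an intercept", {
  cfg <- simulation_config(seed = 29, jitter_cv = 0)
  d <- simulate_dataset(cfg)
  for (ch in c("wue_i", "wue_inst", "ce")) {
    fit <- fit_efficiency(d, ch)
    expect_true(fit$converged)
    emp <- empirical_traits(suppressWarnings(derive_channels(d)), ch)
    # fitted maximum in the neighbourhood of the observed one
    expect_lt(rel_err(fit$mean[["max"]], emp$mean[["y_max"]]), 0.15)
  }
})

test_that("peak light-use efficiency follows its closed form", {
  # closed form against a numeric argmax oracle
  isat <- lue_saturation(pn_ref)
  oracle <- grid_argmax(function(i) ye_response(i, pn_ref) / i, 1, 2400)
  expect_lt(abs(isat - oracle) / oracle, 0.005)
  expect_equal(isat, 318.6, tolerance = 1e-3)
  # no respiration: peak at the dark limit where LUE -> alpha
  p0 <- ye_params(pn_ref$alpha, pn_ref$beta, pn_ref$gamma, offset = 0)
  expect_equal(lue_saturation(p0), 0)
  # doubling respiration strictly raises the optimal irradiance
  p2 <- ye_params(pn_ref$alpha, pn_ref$beta, pn_ref$gamma,
                  offset = 2 * pn_ref$offset)
  expect_gt(lue_saturation(p2), isat)
  expect_gt(lue_saturation(p2) / grid_argmax(
    function(i) ye_response(i, p2) / i, 1, 2400), 0.995)
})

test_that("LUE times irradiance restores the gross response exactly", {
  i <- c(50, 150, 400, 1000, 2400)
  lue <- ye_response(i, pn_ref) / i
  gross <- pn_ref$alpha * (1 - pn_ref$beta * i) / (1 + pn_ref$gamma * i) * i
  expect_equal(lue * i + pn_ref$offset, gross, tolerance = 1e-12)
})

test_that("the LUE channel reuses the assimilation fit", {
  cfg <- simulation_config(seed = 37, jitter_cv = 0)
  fit <- fit_efficiency(simulate_dataset(cfg), "lue")
  expect_lt(rel_err(fit$mean[["i_sat"]], lue_saturation(cfg$pn_params)), 0.1)
  expect_s3_class(fit$pn_fit, "lrc_fit")
})

test_that("fitted and measured efficiency maxima agree under calibrated noise", {
  cfg <- simulation_config(seed = 41, jitter_cv = 0.05)
  d <- simulate_dataset(cfg)
  fit <- fit_efficiency(d, "npq")
  emp <- empirical_traits(d, "npq")
  res <- anova_fitted_vs_measured(list(fitted = fit$per_replicate$max,
                                       measured = emp$per_replicate$y_max))
  expect_gt(res$p_value, 0.05)
  expect_equal(unname(res$letters[1]), unname(res$letters[2]))
})
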