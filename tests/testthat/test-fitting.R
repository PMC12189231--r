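test_that("goodness-of-fit statistics match hand arithmetic", {
  g <- goodness_of_fit(c(1, 2, 3), c(1, 2, 4), k_params = 1)
  expect_equal(g$r_squared, 0.5)
  expect_equal(g$mae, 1 / 3)
  exact <- goodness_of_fit(1:5, 1:5, k_params = 2)
  expect_equal(exact$r_squared, 1)
  expect_equal(exact$mae, 0)
  expect_equal(exact$aic, -Inf)
  # AIC decreases when SSE halves at fixed n, k
  y <- c(0.3, -0.1, 0.2, -0.4, 0.1)
  a1 <- goodness_of_fit(y, y - sqrt(2) * y / 2, 2)$aic # SSE/2
  a0 <- goodness_of_fit(y, rep(0, 5), 2)$aic
  expect_lt(a1, a0)
  expect_true(is.na(goodness_of_fit(rep(2, 4), rep(1, 4), 1)$r_squared))
  expect_error(goodness_of_fit(1:3, 1:4, 1), "equal length")
  expect_error(goodness_of_fit(1:3, 1:3, 3), "more observations")
})

test_that("each family recovers its own parameters exactly at zero noise", {
  gens <- list(
    rh = rh_params(0.0659, 35.93, rd = 3.41),
    nrh = nrh_params(0.0522, 33.70, theta = 0.75, rd = 2.91),
    ye = pn_ref)
  for (m in names(gens)) {
    d <- simulate_curve(gens[[m]], channel = "pn", noise_sd = 0)
    fit <- fit_curve(d, model = m, channel = "pn", mode = "pooled")
    truth <- unlist(unclass(gens[[m]]))
    names(truth)[names(truth) == "offset"] <- "rd"
    expect_lt(max(rel_err(fit$mean_params[names(truth)], truth)), 1e-6)
    expect_equal(fit$r_squared, 1)
    expect_true(fit$converged)
  }
})

test_that("noise strictly lowers the coefficient of determination", {
  clean <- simulate_curve(pn_ref, n_replicates = 2, noise_sd = 0)
  noisy <- simulate_curve(pn_ref, n_replicates = 2, noise_sd = 0.5, seed = 3)
  f0 <- fit_curve(clean, "ye", mode = "pooled")
  f1 <- fit_curve(noisy, "ye", mode = "pooled")
  expect_equal(f0$r_squared, 1)
  expect_lt(f1$r_squared, 1)
})

test_that("per-replicate mode aggregates parameters as mean and SE", {
  d <- simulate_dataset(simulation_config(n_replicates = 4, seed = 5))
  fit <- fit_curve(d, "ye", "pn", mode = "per_replicate")
  expect_equal(nrow(fit$per_replicate_params), 4)
  expect_equal(fit$mean_params,
               colMeans(fit$per_replicate_params))
  expect_equal(fit$se_params,
               apply(fit$per_replicate_params, 2, sd) / 2)
  expect_s3_class(fit$params, "ye_params")
  # initial slope lands near the generating value under default noise
  expect_lt(rel_err(fit$mean_params[["alpha"]], 0.0528), 0.2)
})

test_that("initial slope is recovered across simulated experiments", {
  errs <- vapply(1:20, function(s) {
    cfg <- simulation_config(seed = 100 + s, jitter_cv = 0)
    fit <- fit_curve(simulate_dataset(cfg), "ye", "pn", mode = "pooled")
    rel_err(fit$mean_params[["alpha"]], 0.0528)
  }, 0)
  expect_lt(median(errs), 0.05)
})

test_that("fitting a peaked curve with a hyperbola inflates the asymptote", {
  # Blackman-shaped generating curve: the rectangular hyperbola must
  # overshoot the plateau to chase the sharp bend
  d <- simulate_curve(nrh_params(0.06, 25, theta = 1, rd = 2),
                      noise_sd = 0.2, seed = 9)
  frh <- fit_curve(d, "rh", mode = "pooled")
  expect_gt(frh$mean_params[["pn_max"]], 25)
})

test_that("input validation catches unusable datasets", {
  few <- data.frame(i = c(0, 100, 500, 1000), pn = c(-2, 3, 10, 15))
  expect_error(light_response_dataset(few), "5 distinct light steps")
  d <- simulate_dataset(simulation_config(seed = 1))
  expect_error(fit_curve(d, "ye", channel = "nope"), "not present")
})

test_that("empirical traits interpolate the compensation point", {
  d <- data.frame(i = c(0, 50, 100, 400, 800, 1600),
                  pn = c(-3.4, -0.2, 2.1, 10, 15, 18))
  emp <- empirical_traits(light_response_dataset(d), "pn")
  per <- emp$per_replicate
  expect_equal(per$y_max, 18)
  expect_equal(per$i_at_max, 1600)
  expect_equal(per$y_dark, -3.4)
  # linear interpolation oracle: 50 + 50 * 0.2/2.3
  expect_equal(per$i_c, 50 + 50 * (0.2 / 2.3), tolerance = 1e-12)
  # monotone positive channel has no compensation point
  d2 <- data.frame(i = c(0, 50, 100, 400, 800), npq = c(0, .1, .2, .5, .8))
  expect_true(is.na(empirical_traits(light_response_dataset(d2),
                                     "npq")$per_replicate$i_c))
})

test_that("measured saturation is a member of the light protocol", {
  d <- simulate_dataset(simulation_config(seed = 21))
  emp <- empirical_traits(d, "j")
  expect_true(all(emp$per_replicate$i_at_max %in% default_light_protocol()))
})

test_that("model comparison ranks the generating family first", {
  cfg <- simulation_config(seed = 31, jitter_cv = 0)
  cmp <- compare_models(simulate_dataset(cfg), "pn")
  expect_equal(cmp$table$model[cmp$table$aic_rank == 1], "ye")
  expect_equal(percent_deviation(10, 10), 0)
  # hyperbolic families overestimate the observed maximum
  tab <- cmp$table
  expect_gt(tab$pct_dev_max[tab$model == "rh"], 0)
  expect_gt(tab$pct_dev_max[tab$model == "nrh"], 0)
  # the mechanistic fit tracks it closely
  expect_lt(abs(tab$pct_dev_max[tab$model == "ye"]), 10)
})

test_that("one-way ANOVA and letter display behave on constructed groups", {
  same <- anova_fitted_vs_measured(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$p_value, 1)
  expect_equal(unname(same$letters), c("a", "a"))
  far <- anova_fitted_vs_measured(list(lo = c(1, 2, 3), hi = c(101, 102, 103)))
  expect_lt(far$p_value, 0.001)
  # hand-computed F: SSB/1 = 15000, SSW/4 = 1
  expect_equal(far$f_statistic, 15000, tolerance = 1e-9)
  expect_false(far$letters[["lo"]] == far$letters[["hi"]])
  # only the shifted group earns a distinct letter
  three <- anova_fitted_vs_measured(list(a = c(10.1, 9.9, 10.0),
                                         b = c(10.2, 10.0, 9.8),
                                         c = c(30.1, 29.9, 30.0)))
  expect_equal(three$letters[["a"]], three$letters[["b"]])
  expect_false(three$letters[["c"]] == three$letters[["a"]])
  # degenerate variance reported as such
  flat <- anova_fitted_vs_measured(list(a = c(5, 5), b = c(5, 5)))
  expect_true(flat$degenerate)
  expect_equal(flat$p_value, 1)
  expect_error(anova_fitted_vs_measured(list(a = 1:3)), ">= 2")
})
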