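test_that("rectangular hyperbola evaluates, saturates, and rejects bad input", {
  p <- rh_params(alpha = 0.0659, pn_max = 35.93, rd = 3.41)
  expect_equal(rh_pn(0, p), -3.41)
  # frozen arithmetic oracle: 0.0659*200*35.93/(0.0659*200+35.93) - 3.41
  expect_equal(rh_pn(200, p), 6.23279, tolerance = 1e-6)
  # asymptote pn_max - rd
  expect_equal(rh_pn(1e9, p), 35.93 - 3.41, tolerance = 1e-4)
  # strictly increasing
  grid <- default_light_protocol()
  expect_true(all(diff(rh_pn(sort(grid), p)) > 0))
  expect_error(rh_pn(-1, p), "irradiance")
  expect_error(rh_params(-0.1, 30), "alpha")
})

test_that("non-rectangular hyperbola matches its quadratic-root oracle", {
  # oracle: smaller root of theta*P^2 - (alpha*I+pmax)*P + alpha*I*pmax = 0
  quad_oracle <- function(i, alpha, pmax, theta, rd) {
    a <- alpha * i; s <- a + pmax
    (s - sqrt(s^2 - 4 * theta * a * pmax)) / (2 * theta) - rd
  }
  p <- nrh_params(0.05, 30, theta = 0.5, rd = 3)
  # frozen: (55 - sqrt(1525))/1 - 3
  expect_equal(nrh_pn(500, p), 12.94875, tolerance = 1e-5)
  for (th in c(0.2, 0.5, 0.9, 0.999)) {
    pp <- nrh_params(0.0522, 33.70, theta = th, rd = 2.91)
    i <- c(50, 150, 400, 1000, 2400)
    expect_equal(nrh_pn(i, pp), quad_oracle(i, 0.0522, 33.70, th, 2.91),
                 tolerance = 1e-9)
  }
  expect_error(nrh_params(0.05, 30, theta = 0), "theta")
  expect_error(nrh_params(0.05, 30, theta = 1.2), "theta")
})

test_that("convexity limits: Blackman at theta = 1, rectangular as theta -> 0", {
  a <- 0.0522; pm <- 33.70; rd <- 2.91
  grid <- default_light_protocol()
  black <- nrh_params(a, pm, theta = 1, rd = rd)
  expect_equal(nrh_pn(grid, black), pmin(a * grid, pm) - rd)
  expect_equal(nrh_pn(200, black), min(10.44, 33.70) - 2.91)
  small <- nrh_params(a, pm, theta = 1e-8, rd = rd)
  rh_match <- rh_params(a, pm, rd)
  expect_lt(max(abs(nrh_pn(grid, small) - rh_pn(grid, rh_match))), 1e-5)
})

test_that("mechanistic response evaluates and peaks at its saturation irradiance", {
  expect_equal(ye_response(0, pn_ref), -3.46)
  # trait round trips through the closed forms (printed values are inputs)
  expect_equal(ye_response(ref$pn$i_sat, pn_ref), ref$pn$pn_max,
               tolerance = 1e-6)
  expect_equal(ye_response(ref$j$i_sat, j_ref), ref$j$j_max,
               tolerance = 1e-6)
  # interior maximum then decline when beta > 0
  i <- seq(0, 6000, by = 50)
  y <- ye_response(i, j_ref)
  expect_lt(which.max(y), length(y))
  expect_true(all(diff(y[i > 2000]) < 0))
})

test_that("closed-form maximum and saturation match numeric-optimum oracles", {
  for (p in list(pn_ref, j_ref,
                 ye_params(0.02, 5e-4, 2e-3, offset = 1))) {
    opt <- stats::optimize(function(i) ye_response(i, p),
                           c(0, 3 / p$gamma), maximum = TRUE, tol = 1e-10)
    expect_equal(ye_max(p), opt$objective, tolerance = 1e-7)
    expect_equal(ye_sat_irradiance(p), opt$maximum, tolerance = 1e-5)
    # analytic identity: response at saturation equals the maximum
    expect_equal(ye_response(ye_sat_irradiance(p), p), ye_max(p),
                 tolerance = 1e-12)
  }
  # beta = gamma closed form: I_sat = (sqrt(2)-1)/gamma
  pg <- ye_params(0.1, 2e-3, 2e-3)
  expect_equal(ye_sat_irradiance(pg), (sqrt(2) - 1) / 2e-3, tolerance = 1e-12)
})

test_that("beta = 0 signals no finite maximum or saturation", {
  p0 <- ye_params(0.05, 0, 1e-3)
  expect_error(ye_max(p0), class = "lrc_no_saturation")
  expect_error(ye_sat_irradiance(p0), class = "lrc_no_saturation")
  # monotone saturating towards alpha/gamma
  expect_lt(ye_response(1e8, p0), 0.05 / 1e-3)
  expect_gt(ye_response(1e8, p0), 0.05 / 1e-3 - 1e-2)
})

test_that("quantum efficiency is the derivative of the response", {
  grid <- seq(1, 2400, length.out = 100)
  for (p in list(pn_ref, j_ref)) {
    num <- central_diff(function(i) ye_response(i, p), grid, h = 1e-3)
    expect_lt(max(rel_err(ye_quantum_efficiency(grid, p), num)), 1e-6)
  }
  expect_equal(ye_quantum_efficiency(0, pn_ref), pn_ref$alpha)
  expect_equal(ye_quantum_efficiency(ye_sat_irradiance(pn_ref), pn_ref), 0,
               tolerance = 1e-12)
  # frozen finite-difference oracle value at I = 1000
  expect_equal(ye_quantum_efficiency(1000, pn_ref), 0.0090019,
               tolerance = 1e-4)
  # strictly decreasing, negative beyond saturation
  qe <- ye_quantum_efficiency(grid, j_ref)
  expect_true(all(diff(qe) < 0))
  expect_true(all(ye_quantum_efficiency(
    seq(ye_sat_irradiance(j_ref) + 1, 6000, by = 100), j_ref) < 0))
})

test_that("trait inversion recovers coefficients and round-trips", {
  # published traits -> coefficients (frozen to printed precision)
  expect_equal(signif(j_ref$beta, 4), 1.861e-4)
  expect_equal(signif(j_ref$gamma, 4), 6.831e-4)
  expect_equal(signif(pn_ref$beta, 4), 8.378e-5)
  expect_equal(signif(pn_ref$gamma, 4), 1.085e-3)
  # randomized feasible triples round-trip through the closed forms
  set.seed(11)
  for (k in 1:50) {
    p <- ye_params(runif(1, 0.01, 0.5), 10^runif(1, -5, -3.5),
                   10^runif(1, -3.5, -2.5), offset = runif(1, 0, 5))
    mx <- ye_max(p); st <- ye_sat_irradiance(p)
    q <- invert_ye(p$alpha, mx, st, p$offset)
    expect_equal(q$beta, p$beta, tolerance = 1e-9)
    expect_equal(q$gamma, p$gamma, tolerance = 1e-9)
    expect_equal(ye_max(q), mx, tolerance = 1e-9)
    expect_equal(ye_sat_irradiance(q), st, tolerance = 1e-9)
  }
})

test_that("infeasible trait triples fail naming the violated inequality", {
  # maximum too high for the slope: beta >= 1/sat
  expect_error(invert_ye(0.01, 100, 500), "beta < 1/sat_irradiance")
  # gamma would be non-positive: 1/beta <= 2*sat
  expect_error(invert_ye(0.1, 60, 1000), "2\\*sat_irradiance")
  expect_error(invert_ye(0.05, -4, 2000, offset = 2), "max_value \\+ offset")
})

test_that("light compensation points match root-finding oracles", {
  p_rh <- rh_params(0.0659, 35.93, 3.41)
  # closed form vs frozen arithmetic and vs an independent bisection
  expect_equal(light_compensation(p_rh), 57.17098, tolerance = 1e-5)
  expect_equal(light_compensation(p_rh),
               bisect(function(i) rh_pn(i, p_rh), 0, 1000), tolerance = 1e-6)
  expect_equal(light_compensation(rh_params(0.05, 30, rd = 0)), 0)
  # mechanistic family vs bisection oracle (spec'd ~70.9)
  ic <- light_compensation(pn_ref)
  expect_equal(ic, bisect(function(i) ye_response(i, pn_ref), 0, 2000),
               tolerance = 1e-6)
  expect_equal(ic, 71.0, tolerance = 1e-2)
  # non-rectangular hyperbola vs bisection
  p_nrh <- nrh_params(0.0522, 33.70, 0.8, rd = 2.91)
  expect_equal(light_compensation(p_nrh),
               bisect(function(i) nrh_pn(i, p_nrh), 0, 5000),
               tolerance = 1e-5)
  # respiration exceeding the reachable maximum: no crossing
  expect_error(light_compensation(ye_params(0.001, 1e-3, 1e-2, offset = 5)),
               class = "lrc_no_compensation")
})

test_that("apparent electron requirement is the trait ratio", {
  expect_equal(apparent_electron_requirement(184.10, 24.64), 7.4716,
               tolerance = 1e-4)
  expect_equal(apparent_electron_requirement(186.07, 24.70), 7.5332,
               tolerance = 1e-4)
  expect_equal(apparent_electron_requirement(42, 42), 1)
  expect_error(apparent_electron_requirement(100, 0), "pn_max")
})

test_that("derived_traits dispatches per family", {
  tr <- derived_traits(pn_ref)
  expect_equal(tr$pn_max, ref$pn$pn_max, tolerance = 1e-6)
  expect_equal(tr$i_sat, ref$pn$i_sat, tolerance = 1e-6)
  tr_rh <- derived_traits(rh_params(0.0659, 35.93, 3.41))
  expect_equal(tr_rh$pn_max, 35.93) # asymptotic parameter, no interior max
  expect_true(is.na(tr_rh$i_sat))   # no finite saturation irradiance
})
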