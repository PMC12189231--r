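#' The standard 16-step light protocol
#'
#' Descending irradiance gradient used by automated light-curve programs
#' of leaf-chamber fluorometers: 2400, 2200, 2000, 1800, 1600, 1400,
#' 1200, 1000, 800, 600, 400, 200, 150, 100, 50, 0 umol photons m^-2
#' s^-1.
#'
#' @return Numeric vector of 16 irradiance steps, descending.
#' @export
default_light_protocol <- function() {
  c(2400, 2200, 2000, 1800, 1600, 1400, 1200, 1000, 800, 600, 400, 200,
    150, 100, 50, 0)
}

#' Configuration for the synthetic light-curve generator
#'
#' Defines the study conditions a simulated experiment emulates. Defaults
#' reproduce the reference water-hyacinth experiment
#' ([reference_traits()]): the 16-step descending light protocol, 4
#' replicates, net assimilation and electron transport curves from the
#' mechanistic family with coefficients obtained by closed-form inversion
#' of the reference fitted traits, and channel coupling (PSII efficiency
#' tied to the electron transport curve through
#' `J = PhiPSII * I * 0.5 * absorptance`; intercellular CO2, stomatal
#' conductance and transpiration tied to net assimilation through a
#' rising-saturating conductance response). Channel noise is additive
#' Gaussian; replicate heterogeneity is lognormal jitter on the true
#' parameters.
#'
#' @param light_protocol Irradiance steps; must be nonnegative with
#'   exactly one dark (0) step and >= 5 distinct values.
#' @param n_replicates Number of replicates (>= 1).
#' @param pn_params,j_params [ye_params()] objects generating the net
#'   assimilation and electron transport channels.
#' @param npq_params [ye_params()] object generating non-photochemical
#'   quenching (rising-saturating, zero in darkness).
#' @param noise_sd Named numeric vector of per-channel Gaussian noise
#'   standard deviations; defaults
#'   `c(pn = 0.3, j = 2, phipsii = 0.01, npq = 0.03, gs = 0.02, tr = 0.3,
#'   ci = 5)` (channel units).
#' @param jitter_cv Lognormal coefficient of variation of the replicate
#'   level parameter jitter (default 0.05; 0 disables heterogeneity).
#' @param absorptance Leaf absorptance in the electron transport
#'   convention `J = PhiPSII * I * 0.5 * absorptance` (default 0.84).
#' @param gs_range `c(min, max)` stomatal conductance, mol m^-2 s^-1.
#' @param gs_k Irradiance of half-maximal stomatal opening.
#' @param tr_per_gs Transpiration per unit conductance, mmol mol^-1
#'   (bundles the vapour pressure gradient).
#' @param ca Chamber CO2, umol mol^-1.
#' @param chl Chlorophyll content metadata, mg m^-2.
#' @param leaf_area Chamber leaf area metadata, m^2.
#' @param seed Integer seed making the dataset reproducible.
#' @return Class `"lrc_sim_config"`.
#' @export
simulation_config <- function(light_protocol = default_light_protocol(),
                              n_replicates = 4,
                              pn_params = NULL, j_params = NULL,
                              npq_params = NULL,
                              noise_sd = NULL,
                              jitter_cv = 0.05,
                              absorptance = 0.84,
                              gs_range = c(0.15, 0.55),
                              gs_k = 300,
                              tr_per_gs = 23.4,
                              ca = 390,
                              chl = 707.34,
                              leaf_area = 2e-4,
                              seed = 1L) {
  if (any(light_protocol < 0) || sum(light_protocol == 0) != 1 ||
      length(unique(light_protocol)) < 5) {
    stop("`light_protocol` must be nonnegative irradiances with exactly one ",
         "dark step and >= 5 distinct values", call. = FALSE)
  }
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    stop("`n_replicates` must be >= 1", call. = FALSE)
  }
  tr <- reference_traits()
  if (is.null(pn_params)) {
    pn_params <- invert_ye(tr$pn$alpha, tr$pn$pn_max, tr$pn$i_sat,
                           offset = tr$pn$rd)
  }
  if (is.null(j_params)) {
    j_params <- invert_ye(tr$j$alpha, tr$j$j_max, tr$j$i_sat)
  }
  if (is.null(npq_params)) {
    npq_params <- invert_ye(0.0015, tr$efficiency$npq$max_fitted,
                            tr$efficiency$npq$i_sat_fitted)
  }
  stopifnot(inherits(pn_params, "ye_params"), inherits(j_params, "ye_params"),
            inherits(npq_params, "ye_params"))
  defaults <- c(pn = 0.3, j = 2, phipsii = 0.01, npq = 0.03, gs = 0.02,
                tr = 0.3, ci = 5)
  if (is.null(noise_sd)) noise_sd <- defaults
  miss <- setdiff(names(defaults), names(noise_sd))
  noise_sd <- c(noise_sd, defaults[miss])[names(defaults)]
  if (any(noise_sd < 0)) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (jitter_cv < 0) stop("`jitter_cv` must be >= 0", call. = FALSE)
  if (length(gs_range) != 2 || any(gs_range <= 0) || diff(gs_range) < 0) {
    stop("`gs_range` must be c(min, max) with 0 < min <= max", call. = FALSE)
  }
  structure(list(light_protocol = light_protocol,
                 n_replicates = as.integer(n_replicates),
                 pn_params = pn_params, j_params = j_params,
                 npq_params = npq_params, noise_sd = noise_sd,
                 jitter_cv = jitter_cv, absorptance = absorptance,
                 gs_range = gs_range, gs_k = gs_k, tr_per_gs = tr_per_gs,
                 ca = ca, chl = chl, leaf_area = leaf_area,
                 seed = as.integer(seed)),
            class = "lrc_sim_config")
}

jitter_params <- function(p, cv) {
  if (cv == 0) return(p)
  sdlog <- sqrt(log(1 + cv^2))
  jit <- function(x) if (x > 0) x * stats::rlnorm(1, -sdlog^2 / 2, sdlog) else x
  ye_params(jit(p$alpha), jit(p$beta), jit(p$gamma), jit(p$offset))
}

#' Simulate a replicate-structured light-curve dataset
#'
#' Draws one synthetic experiment under a [simulation_config()]: for each
#' replicate, the true parameters receive lognormal jitter, channel means
#' are computed from the forward models, coupled channels are derived
#' (`phipsii = J / (0.5 * absorptance * I)`, conductance rising-saturating
#' in irradiance, `tr` proportional to conductance,
#' `ci = ca - pn / (gs / 1.6)`), and independent Gaussian noise is added
#' per channel. Fixing the seed fixes the dataset exactly.
#'
#' @param config An `"lrc_sim_config"`.
#' @return An `lrc_dataset` with channels `pn`, `j`, `phipsii`, `npq`,
#'   `gs`, `tr`, `ci`, and the generating truth attached as attribute
#'   `"truth"` (list of per-replicate parameter sets).
#' @examples
#' d <- simulate_dataset(simulation_config(n_replicates = 2, seed = 42))
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "lrc_sim_config"))
  set.seed(config$seed)
  i <- config$light_protocol
  n <- length(i)
  truth <- list()
  rows <- lapply(seq_len(config$n_replicates), function(r) {
    pn_p <- jitter_params(config$pn_params, config$jitter_cv)
    j_p <- jitter_params(config$j_params, config$jitter_cv)
    npq_p <- jitter_params(config$npq_params, config$jitter_cv)
    truth[[r]] <<- list(pn = pn_p, j = j_p, npq = npq_p)
    pn_mean <- ye_response(i, pn_p)
    j_mean <- ye_response(i, j_p)
    phi_mean <- ifelse(i > 0, j_mean / (0.5 * config$absorptance * i),
                       j_p$alpha / (0.5 * config$absorptance))
    npq_mean <- ye_response(i, npq_p)
    gs_mean <- config$gs_range[1] +
      diff(config$gs_range) * i / (i + config$gs_k)
    tr_mean <- config$tr_per_gs * gs_mean
    ci_mean <- config$ca - pn_mean / (gs_mean / 1.6)
    ns <- config$noise_sd
    data.frame(
      replicate = r, i = i,
      pn = pn_mean + stats::rnorm(n, 0, ns[["pn"]]),
      j = pmax(j_mean + stats::rnorm(n, 0, ns[["j"]]), 0),
      phipsii = pmin(pmax(phi_mean + stats::rnorm(n, 0, ns[["phipsii"]]), 0), 1),
      npq = pmax(npq_mean + stats::rnorm(n, 0, ns[["npq"]]), 0),
      gs = pmax(gs_mean + stats::rnorm(n, 0, ns[["gs"]]), 1e-3),
      tr = pmax(tr_mean + stats::rnorm(n, 0, ns[["tr"]]), 1e-3),
      ci = pmax(ci_mean + stats::rnorm(n, 0, ns[["ci"]]), 1))
  })
  out <- light_response_dataset(
    do.call(rbind, rows),
    leaf_area = config$leaf_area, chl = config$chl, ca = config$ca,
    extra_metadata = list(seed = config$seed,
                          absorptance = config$absorptance))
  attr(out, "truth") <- truth
  out
}

#' Simulate a single-channel dataset from any model family
#'
#' Generates a dataset holding one channel directly from a forward model
#' (no channel coupling), for identifiability and recovery checks of a
#' specific family.
#'
#' @param params An `lrc_params` object (any family).
#' @param channel Channel name for the generated column.
#' @param light_protocol Irradiance steps.
#' @param n_replicates Number of replicates.
#' @param noise_sd Gaussian noise SD (0 gives exact forward-model values).
#' @param seed Optional seed.
#' @return An `lrc_dataset`.
#' @examples
#' p <- ye_params(0.05, 1e-4, 1e-3, offset = 3)
#' d <- simulate_curve(p, noise_sd = 0)
#' @export
simulate_curve <- function(params, channel = "pn",
                           light_protocol = default_light_protocol(),
                           n_replicates = 1, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "lrc_params"))
  if (!is.null(seed)) set.seed(seed)
  fwd <- switch(class(params)[1],
                rh_params = function(i) rh_pn(i, params),
                nrh_params = function(i) nrh_pn(i, params),
                ye_params = function(i) ye_response(i, params))
  rows <- lapply(seq_len(n_replicates), function(r) {
    y <- fwd(light_protocol) +
      stats::rnorm(length(light_protocol), 0, noise_sd)
    out <- data.frame(replicate = r, i = light_protocol)
    out[[channel]] <- y
    out
  })
  light_response_dataset(do.call(rbind, rows))
}

#' Repeated simulate-and-fit recovery experiment
#'
#' Runs `n_seeds` independent simulate/fit cycles and summarises how well
#' a model family recovers the generating parameters and the derived
#' traits (maximum response, saturation irradiance): per-parameter bias,
#' RMSE and median relative error, plus per-seed fit failures.
#'
#' @param config An `"lrc_sim_config"`; its `seed` anchors the seed
#'   sequence `seed, seed + 1, ...` used for the replicate datasets.
#' @param model Family to fit (`"ye"`, `"rh"`, `"nrh"`).
#' @param channel Channel to fit (default `"pn"`).
#' @param n_seeds Number of independent simulated experiments (>= 2).
#' @param mode Fitting mode passed to [fit_curve()].
#' @return Class `"lrc_recovery"`: list with `estimates` (one row per
#'   seed), `truth`, `summary` (bias, RMSE, median relative error per
#'   quantity), `n_failed`.
#' @export
recovery_experiment <- function(config, model = "ye", channel = "pn",
                                n_seeds = 100, mode = "pooled") {
  stopifnot(inherits(config, "lrc_sim_config"))
  if (n_seeds < 2) stop("`n_seeds` must be >= 2", call. = FALSE)
  truth_p <- switch(channel, pn = config$pn_params, j = config$j_params,
                    npq = config$npq_params,
                    stop("recovery supports channels pn, j, npq",
                         call. = FALSE))
  truth <- c(unlist(truth_p[c("alpha", "beta", "gamma", "offset")]),
             max = ye_max(truth_p), i_sat = ye_sat_irradiance(truth_p))
  rows <- lapply(seq_len(n_seeds), function(k) {
    cfg <- config
    cfg$seed <- config$seed + k - 1L
    d <- simulate_dataset(cfg)
    fit <- tryCatch(fit_curve(d, model, channel, mode = mode),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(seed = cfg$seed, converged = FALSE,
                        alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
                        offset = NA_real_, max = NA_real_, i_sat = NA_real_))
    }
    p <- fit$params
    tr <- derived_traits(p)
    data.frame(seed = cfg$seed, converged = fit$converged,
               alpha = p$alpha,
               beta = if (inherits(p, "ye_params")) p$beta else NA_real_,
               gamma = if (inherits(p, "ye_params")) p$gamma else NA_real_,
               offset = if (inherits(p, "ye_params")) p$offset else p$rd,
               max = tr$pn_max, i_sat = tr$i_sat)
  })
  est <- do.call(rbind, rows)
  qty <- c("alpha", "beta", "gamma", "offset", "max", "i_sat")
  summ <- do.call(rbind, lapply(qty, function(q) {
    v <- est[[q]][is.finite(est[[q]])]
    tv <- truth[[q]]
    if (length(v) == 0 || !is.finite(tv)) {
      return(data.frame(quantity = q, truth = tv, bias = NA_real_,
                        rmse = NA_real_, median_rel_error = NA_real_))
    }
    data.frame(quantity = q, truth = tv, bias = mean(v) - tv,
               rmse = sqrt(mean((v - tv)^2)),
               median_rel_error = stats::median(abs(v - tv) / abs(tv)))
  }))
  structure(list(estimates = est, truth = truth, summary = summ,
                 n_failed = sum(!est$converged)),
            class = "lrc_recovery")
}

#' @export
print.lrc_recovery <- function(x, ...) {
  cat("Parameter-recovery experiment over", nrow(x$estimates), "seeds (",
      x$n_failed, "failed )\n")
  s <- x$summary
  s[-1] <- lapply(s[-1], function(v) signif(v, 4))
  print(s, row.names = FALSE)
  invisible(x)
}
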