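#' Write a structured JSON analysis report
#'
#' Serialises fit results, trait tables and pigment derivations into a
#' single JSON document with stable key order, suitable for diffing
#' across runs: identical inputs produce byte-identical reports.
#'
#' @param path Output path for the JSON document.
#' @param fits Named list of `lrc_fit` and/or `lrc_efficiency_fit`
#'   objects (at least one entry).
#' @param empirical Optional [empirical_traits()] result (or a named list
#'   of them).
#' @param comparison Optional [compare_models()] result.
#' @param pigments Optional [pigment_traits()] result.
#' @param config Optional [simulation_config()] (echoed for provenance).
#' @param seed Optional integer seed echoed into the report.
#' @return `path`, invisibly.
#' @export
write_report <- function(path, fits, empirical = NULL, comparison = NULL,
                         pigments = NULL, config = NULL, seed = NULL) {
  if (!is.list(fits) || length(fits) == 0) {
    stop("`fits` must be a non-empty list", call. = FALSE)
  }
  doc <- list(
    package = "lrcfit",
    version = as.character(utils::packageVersion("lrcfit")),
    seed = seed,
    fits = lapply(fits, serialise_fit),
    empirical = serialise_empirical(empirical),
    comparison = if (!is.null(comparison)) comparison$table,
    pigments = serialise_pigments(pigments),
    config = serialise_config(config))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

serialise_fit <- function(f) {
  if (inherits(f, "lrc_fit")) {
    list(model = f$model, channel = f$channel, mode = f$mode,
         mean_params = as.list(f$mean_params),
         se_params = as.list(f$se_params),
         r_squared = f$r_squared, mae = f$mae, aic = f$aic,
         n_obs = f$n_obs, converged = f$converged,
         n_iterations = f$n_iterations)
  } else if (inherits(f, "lrc_efficiency_fit")) {
    list(channel = f$channel,
         trait_mean = as.list(f$mean), trait_se = as.list(f$se),
         r_squared = f$r_squared, mae = f$mae, converged = f$converged)
  } else {
    stop("unserialisable fit object of class ", class(f)[1], call. = FALSE)
  }
}

serialise_empirical <- function(e) {
  if (is.null(e)) return(NULL)
  if (inherits(e, "lrc_empirical_traits")) {
    return(list(channel = e$channel, mean = as.list(e$mean),
                se = as.list(e$se)))
  }
  lapply(e, serialise_empirical)
}

serialise_pigments <- function(p) {
  if (is.null(p)) return(NULL)
  list(n0 = p$n0, n0_per_area = p$n0_per_area, sigma_ik = p$sigma_ik,
       tau = p$tau, chl = p$chl, s = p$s, k_product = p$k_product,
       profiles = p$profiles)
}

serialise_config <- function(cfg) {
  if (is.null(cfg)) return(NULL)
  list(light_protocol = cfg$light_protocol,
       n_replicates = cfg$n_replicates,
       pn_params = unclass(cfg$pn_params),
       j_params = unclass(cfg$j_params),
       npq_params = unclass(cfg$npq_params),
       noise_sd = as.list(cfg$noise_sd),
       jitter_cv = cfg$jitter_cv, absorptance = cfg$absorptance,
       gs_range = cfg$gs_range, gs_k = cfg$gs_k,
       tr_per_gs = cfg$tr_per_gs, ca = cfg$ca, chl = cfg$chl,
       leaf_area = cfg$leaf_area, seed = cfg$seed)
}
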