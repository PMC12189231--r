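#' Goodness-of-fit statistics
#'
#' Computes the three statistics used for model comparison:
#' `R^2 = 1 - SSE/SST` (SST centred on the observed mean), the mean
#' absolute error `MAE = mean(|predicted - observed|)`, and the
#' Gaussian-likelihood Akaike criterion
#' `AIC = n*log(SSE/n) + 2*(k_params + 1)` (the `+1` counts the error
#' variance). Only AIC differences between models fitted to the same data
#' are meaningful.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @param k_params Number of fitted model parameters; must be < n.
#' @return A list with `r_squared` (`NA` when SST is zero), `mae`, `aic`
#'   (`-Inf` for an exact fit).
#' @examples
#' goodness_of_fit(c(1, 2, 3), c(1, 2, 4), k_params = 1)
#' @export
goodness_of_fit <- function(observed, predicted, k_params) {
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal length", call. = FALSE)
  }
  n <- length(observed)
  if (n <= k_params) {
    stop("need more observations than parameters (n = ", n,
         ", k = ", k_params, ")", call. = FALSE)
  }
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sse / sst
  aic <- if (sse == 0) -Inf else n * log(sse / n) + 2 * (k_params + 1)
  list(r_squared = r2, mae = mean(abs(predicted - observed)), aic = aic)
}

# ---- internal model registry -------------------------------------------

# Each family is described by parameter names, box bounds, a prediction
# function over a raw parameter vector, data-driven starting values, and a
# conversion to the user-facing parameter classes. The offset (dark
# respiration) is a free parameter only for channels that are negative in
# darkness (net CO2 assimilation); for all others it is fixed at zero.
model_spec <- function(model, with_offset) {
  base <- switch(model,
    rh = list(
      names = c("alpha", "pn_max"),
      lower = c(1e-6, 1e-3), upper = c(1, 1e4),
      pred = function(i, par, off) {
        par[1] * i * par[2] / (par[1] * i + par[2]) - off
      },
      to_params = function(par, off) rh_params(par[1], par[2], off)),
    nrh = list(
      names = c("alpha", "pn_max", "theta"),
      lower = c(1e-6, 1e-3, 1e-3), upper = c(1, 1e4, 1),
      pred = function(i, par, off) {
        a <- par[1] * i; s <- a + par[2]
        disc <- pmax(s^2 - 4 * par[3] * a * par[2], 0)
        ifelse(i == 0, 0, 2 * a * par[2] / (s + sqrt(disc))) - off
      },
      to_params = function(par, off) nrh_params(par[1], par[2], par[3], off)),
    ye = list(
      names = c("alpha", "beta", "gamma"),
      lower = c(1e-6, 0, 1e-6), upper = c(1, 1e-2, 1e-1),
      pred = function(i, par, off) {
        par[1] * (1 - par[2] * i) / (1 + par[3] * i) * i - off
      },
      to_params = function(par, off) ye_params(par[1], par[2], par[3], off)),
    stop("unknown model `", model, "` (use \"rh\", \"nrh\" or \"ye\")",
         call. = FALSE)
  )
  if (with_offset) {
    base$names <- c(base$names, "rd")
    base$lower <- c(base$lower, 0)
    base$upper <- c(base$upper, 20)
    inner <- base$pred
    base$pred2 <- function(i, par) inner(i, par, par[length(par)])
    conv <- base$to_params
    base$to_params2 <- function(par) conv(par, par[length(par)])
  } else {
    inner <- base$pred
    base$pred2 <- function(i, par) inner(i, par, 0)
    conv <- base$to_params
    base$to_params2 <- function(par) conv(par, 0)
  }
  base$k <- length(base$names)
  base
}

# Deterministic data-driven starting values: initial slope from an OLS
# line through the three lowest nonzero light steps, offset from the dark
# observation, asymptote from the channel maximum, theta at mid-range,
# and (beta, gamma) from the closed-form trait inversion applied to the
# observed maximum and its irradiance.
start_values <- function(spec, model, i, y, with_offset) {
  rd0 <- 0
  if (with_offset && any(i == 0)) rd0 <- max(0, -mean(y[i == 0]))
  gross <- y + rd0
  steps <- sort(unique(i[i > 0]))
  low <- i %in% utils::head(steps, 3)
  a0 <- sum(gross[low] * i[low]) / sum(i[low]^2)
  a0 <- min(1, max(1e-4, a0))
  ymax <- max(gross)
  st <- switch(model,
    rh = c(a0, max(ymax, 1e-2)),
    nrh = c(a0, max(ymax, 1e-2), 0.5),
    ye = {
      isat0 <- i[which.max(gross)]
      bg <- tryCatch({
        p <- invert_ye(a0, max(ymax - rd0, 1e-3), max(isat0, 1), rd0)
        c(p$beta, p$gamma)
      }, error = function(e) c(1e-4, 1e-3))
      c(a0, bg)
    })
  if (with_offset) st <- c(st, rd0)
  pmin(pmax(st, spec$lower + 1e-12), spec$upper)
}

fit_one <- function(spec, i, y, init, lower, upper, max_iter) {
  out <- minpack.lm::nls.lm(
    par = init,
    lower = lower, upper = upper,
    fn = function(par) y - spec$pred2(i, par),
    control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                         maxfev = 100 * (spec$k + 1) * 50))
  par <- stats::setNames(out$par, spec$names)
  list(par = par,
       converged = out$info %in% 1:4,
       niter = out$niter,
       fitted = spec$pred2(i, par))
}

#' Fit a light-response model to a dataset channel
#'
#' Nonlinear least squares (trust-region Levenberg-Marquardt) for one model
#' family on one response channel. In `per_replicate` mode (the default,
#' matching the replicate structure of light-curve experiments) each
#' replicate is fitted separately and the parameters are aggregated as
#' mean +/- SE (SE = SD/sqrt(n)); the reported goodness-of-fit statistics
#' are the means of the per-replicate statistics. In `pooled` mode all
#' observations are fitted jointly. Starting values are deterministic and
#' data-driven (see Details), so the fit is reproducible without random
#' restarts.
#'
#' @details Starting values: the initial slope from an ordinary
#' least-squares line through the three lowest nonzero light steps, dark
#' respiration from the dark observation, the asymptote from the channel
#' maximum, convexity 0.5, and the photoinhibition/saturation coefficients
#' from the closed-form trait inversion ([invert_ye()]) applied to the
#' observed maximum and its light step. Box bounds keep parameters in
#' physically meaningful ranges (initial slope in (0, 1], photoinhibition
#' coefficient in [0, 1e-2], saturation coefficient in (0, 0.1], convexity
#' in (0.001, 1], respiration in [0, 20]).
#'
#' @param dataset An `lrc_dataset` (or a data.frame accepted by
#'   [light_response_dataset()]).
#' @param model `"rh"`, `"nrh"` or `"ye"`.
#' @param channel Response channel column to fit (default `"pn"`). The
#'   offset (dark respiration) is a free parameter for `"pn"` and fixed at
#'   zero otherwise.
#' @param mode `"per_replicate"` or `"pooled"`.
#' @param init Optional named numeric vector of starting values.
#' @param bounds Optional list with elements `lower`/`upper` overriding the
#'   default box bounds.
#' @param max_iter Iteration cap; exceeding it flags the report as
#'   non-converged rather than raising an error.
#' @return An object of class `"lrc_fit"`: model and channel ids, per
#'   replicate parameter table, `mean_params`, `se_params`, the mean
#'   parameter set as an `lrc_params` object (`$params`), `r_squared`,
#'   `mae`, `aic`, `residuals`, `n_obs`, `converged`, `n_iterations`, and
#'   `per_replicate_stats`.
#' @examples
#' cfg <- simulation_config(n_replicates = 2, seed = 1)
#' fit <- fit_curve(simulate_dataset(cfg), model = "ye", channel = "pn")
#' fit$mean_params
#' @export
fit_curve <- function(dataset, model = c("ye", "rh", "nrh"), channel = "pn",
                      mode = c("per_replicate", "pooled"), init = NULL,
                      bounds = NULL, max_iter = 1000) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  if (is.data.frame(dataset)) dataset <- light_response_dataset(dataset)
  stopifnot(inherits(dataset, "lrc_dataset"))
  require_channel(dataset, channel)
  d <- dataset$data[is.finite(dataset$data[[channel]]), ]
  if (length(unique(d$i)) < 5) {
    stop("need at least 5 distinct light steps to fit", call. = FALSE)
  }
  with_offset <- channel == "pn"
  spec <- model_spec(model, with_offset)
  if (length(unique(d$i)) <= spec$k) {
    stop("fewer distinct light steps than parameters", call. = FALSE)
  }
  lower <- if (!is.null(bounds$lower)) bounds$lower else spec$lower
  upper <- if (!is.null(bounds$upper)) bounds$upper else spec$upper

  groups <- if (mode == "per_replicate") split(d, d$replicate) else list(all = d)
  reps <- lapply(groups, function(g) {
    st <- if (!is.null(init)) init[spec$names] else
      start_values(spec, model, g$i, g[[channel]], with_offset)
    f <- fit_one(spec, g$i, g[[channel]], st, lower, upper, max_iter)
    f$gof <- goodness_of_fit(g[[channel]], f$fitted, spec$k)
    f$residuals <- g[[channel]] - f$fitted
    f
  })

  par_mat <- do.call(rbind, lapply(reps, function(f) f$par))
  mean_params <- colMeans(par_mat)
  se_params <- if (nrow(par_mat) >= 2) {
    apply(par_mat, 2, stats::sd) / sqrt(nrow(par_mat))
  } else {
    stats::setNames(rep(NA_real_, spec$k), spec$names)
  }
  stats_tab <- data.frame(
    replicate = names(reps),
    r_squared = vapply(reps, function(f) f$gof$r_squared, 0),
    mae = vapply(reps, function(f) f$gof$mae, 0),
    aic = vapply(reps, function(f) f$gof$aic, 0),
    converged = vapply(reps, function(f) f$converged, TRUE),
    n_iterations = vapply(reps, function(f) f$niter, 0L),
    row.names = NULL)

  structure(list(
    model = model, channel = channel, mode = mode,
    per_replicate_params = par_mat,
    mean_params = mean_params,
    se_params = se_params,
    params = spec$to_params2(mean_params),
    replicate_params = lapply(seq_len(nrow(par_mat)),
                              function(r) spec$to_params2(par_mat[r, ])),
    r_squared = mean(stats_tab$r_squared),
    mae = mean(stats_tab$mae),
    aic = mean(stats_tab$aic),
    residuals = unlist(lapply(reps, function(f) f$residuals), use.names = FALSE),
    n_obs = nrow(d),
    k_params = spec$k,
    converged = all(stats_tab$converged),
    n_iterations = max(stats_tab$n_iterations),
    per_replicate_stats = stats_tab
  ), class = "lrc_fit")
}

#' @export
print.lrc_fit <- function(x, ...) {
  cat(sprintf("Light-response fit: %s model, channel `%s` (%s, %d obs)\n",
              toupper(x$model), x$channel, x$mode, x$n_obs))
  est <- signif(x$mean_params, 5)
  se <- signif(x$se_params, 3)
  for (nm in names(est)) {
    cat(sprintf("  %-7s %-12s %s\n", nm, est[[nm]],
                if (is.finite(se[[nm]])) paste0("+/- ", se[[nm]]) else ""))
  }
  cat(sprintf("  R^2 = %.4f  MAE = %.3f  AIC = %.2f  converged: %s\n",
              x$r_squared, x$mae, x$aic, x$converged))
  invisible(x)
}

#' Empirical (model-free) trait estimates
#'
#' Per replicate: the channel maximum, the light step at which the maximum
#' is observed (the measured saturation irradiance), the dark value (its
#' negative is the measured dark respiration for the net CO2 channel), and
#' the measured light compensation point by linear interpolation between
#' the adjacent light steps where the response crosses zero. Traits are
#' aggregated as mean +/- SE across replicates.
#'
#' @param dataset An `lrc_dataset`.
#' @param channel Channel to summarise.
#' @return Class `"lrc_empirical_traits"`: list with `per_replicate`
#'   (data.frame of `y_max`, `i_at_max`, `y_dark`, `i_c`), `mean`, `se`.
#'   `i_c` is `NA` for replicates with no zero crossing.
#' @export
empirical_traits <- function(dataset, channel = "pn") {
  if (is.data.frame(dataset)) dataset <- light_response_dataset(dataset)
  require_channel(dataset, channel)
  d <- dataset$data[is.finite(dataset$data[[channel]]), ]
  per <- do.call(rbind, lapply(split(d, d$replicate), function(g) {
    g <- g[order(g$i), ]
    y <- g[[channel]]
    data.frame(
      replicate = g$replicate[1],
      y_max = max(y),
      i_at_max = g$i[which.max(y)],
      y_dark = if (any(g$i == 0)) mean(y[g$i == 0]) else NA_real_,
      i_c = interpolate_zero_crossing(g$i, y))
  }))
  row.names(per) <- NULL
  num <- per[, c("y_max", "i_at_max", "y_dark", "i_c")]
  agg_mean <- colMeans(num, na.rm = TRUE)
  agg_se <- apply(num, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
  })
  structure(list(channel = channel, per_replicate = per,
                 mean = agg_mean, se = agg_se),
            class = "lrc_empirical_traits")
}

interpolate_zero_crossing <- function(i, y) {
  idx <- which(y[-length(y)] < 0 & y[-1] >= 0)
  if (length(idx) == 0) return(NA_real_)
  k <- idx[1]
  i[k] + (i[k + 1] - i[k]) * (0 - y[k]) / (y[k + 1] - y[k])
}

#' Percent deviation of a fitted trait from its measured value
#'
#' `100 * (fitted - measured) / measured`, the signed overestimation
#' percentage used in fitted-vs-measured trait comparison.
#'
#' @param fitted,measured Numeric (vectorised).
#' @return Percent deviation.
#' @examples
#' percent_deviation(232.08, 186.07) # hyperbolic overestimate of J_max
#' @export
percent_deviation <- function(fitted, measured) {
  100 * (fitted - measured) / measured
}

#' Fit and rank all model families on one channel
#'
#' Fits the requested families, ranks them by AIC, and reports each
#' family's derived traits next to the model-free empirical traits with
#' percent deviations ([percent_deviation()]). Traits are computed per
#' replicate and then averaged (mean of per-replicate trait values), the
#' convention that matches replicate-structured reporting of nonlinear
#' trait means.
#'
#' @param dataset An `lrc_dataset`.
#' @param channel Channel to compare on (default `"pn"`).
#' @param models Character vector of families to include.
#' @param mode Fitting mode passed to [fit_curve()].
#' @return Class `"lrc_model_comparison"`: list with `table` (one row per
#'   model: goodness of fit, AIC rank, mean fitted traits, percent
#'   deviations from measured), `fits` (the `lrc_fit` objects) and
#'   `empirical` (the [empirical_traits()] result).
#' @export
compare_models <- function(dataset, channel = "pn",
                           models = c("rh", "nrh", "ye"),
                           mode = "per_replicate") {
  if (is.data.frame(dataset)) dataset <- light_response_dataset(dataset)
  fits <- lapply(models, function(m) fit_curve(dataset, m, channel, mode))
  names(fits) <- models
  emp <- empirical_traits(dataset, channel)
  rows <- lapply(models, function(m) {
    f <- fits[[m]]
    tr <- do.call(rbind, lapply(f$replicate_params, function(p) {
      as.data.frame(derived_traits(p))
    }))
    max_mean <- mean(tr$pn_max)
    isat_mean <- if (all(is.na(tr$i_sat))) NA_real_ else mean(tr$i_sat)
    ic_mean <- if (all(is.na(tr$i_c))) NA_real_ else mean(tr$i_c, na.rm = TRUE)
    data.frame(
      model = m, r_squared = f$r_squared, mae = f$mae, aic = f$aic,
      converged = f$converged,
      max_fitted = max_mean,
      i_sat_fitted = isat_mean,
      i_c_fitted = ic_mean,
      max_measured = emp$mean[["y_max"]],
      pct_dev_max = percent_deviation(max_mean, emp$mean[["y_max"]]),
      pct_dev_i_sat = if (is.na(isat_mean)) NA_real_ else
        percent_deviation(isat_mean, emp$mean[["i_at_max"]]))
  })
  tab <- do.call(rbind, rows)
  tab$aic_rank <- rank(tab$aic, ties.method = "first")
  tab <- tab[order(tab$aic_rank), ]
  row.names(tab) <- NULL
  structure(list(table = tab, fits = fits, empirical = emp,
                 channel = channel),
            class = "lrc_model_comparison")
}

#' @export
print.lrc_model_comparison <- function(x, ...) {
  cat("Model comparison on channel `", x$channel, "` (ranked by AIC):\n",
      sep = "")
  show <- x$table[, c("model", "r_squared", "mae", "aic", "max_fitted",
                      "pct_dev_max")]
  show[-1] <- lapply(show[-1], function(v) signif(v, 5))
  print(show, row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA with compact letter display
#'
#' Compares fitted against measured trait values (or any set of groups)
#' with a one-way ANOVA F-test at alpha = 0.05 and assigns compact letter
#' groupings from Tukey honest-significant-difference pairwise
#' comparisons: groups sharing a letter are not significantly different.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values).
#' @param alpha Significance level for both the F-test and the letters.
#' @return A list with `p_value`, `f_statistic`, `df`, `means`,
#'   `letters` (named character vector) and `pairwise` (Tukey table, or
#'   `NULL` when degenerate).
#' @examples
#' anova_fitted_vs_measured(list(fitted = c(24.1, 24.9, 25.0, 24.5),
#'                               measured = c(24.3, 25.2, 24.6, 24.8)))
#' @export
anova_fitted_vs_measured <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("`groups` must be a list of >= 2 numeric vectors", call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  if (any(lengths(groups) < 2)) {
    stop("each group needs >= 2 values", call. = FALSE)
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups)))
  means <- tapply(df$value, df$group, mean)
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  p <- tab[["Pr(>F)"]][1]
  if (!is.finite(p)) {
    # zero residual variance: groups are internally constant
    same <- length(unique(means)) == 1
    return(list(p_value = if (same) 1 else 0, f_statistic = NA_real_,
                df = tab[["Df"]], means = means,
                letters = if (same)
                  stats::setNames(rep("a", length(means)), names(means))
                else stats::setNames(letters[order(order(-means))], names(means)),
                pairwise = NULL, degenerate = TRUE))
  }
  tk <- stats::TukeyHSD(fit)$group
  pmat <- matrix(FALSE, length(means), length(means),
                 dimnames = list(names(means), names(means)))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (r in seq_along(pairs)) {
    g1 <- pairs[[r]][1]; g2 <- pairs[[r]][2]
    sig <- tk[r, "p adj"] < alpha
    pmat[g1, g2] <- sig; pmat[g2, g1] <- sig
  }
  list(p_value = p, f_statistic = tab[["F value"]][1], df = tab[["Df"]],
       means = means, letters = letter_display(means, pmat),
       pairwise = tk, degenerate = FALSE)
}

# Compact letter display from a logical "significantly different" matrix:
# greedy clique cover in descending-mean order.
letter_display <- function(means, sig) {
  ord <- names(sort(means, decreasing = TRUE))
  sets <- list()
  for (g in ord) {
    placed <- FALSE
    for (s in seq_along(sets)) {
      if (!any(sig[g, sets[[s]]])) {
        sets[[s]] <- c(sets[[s]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- g
  }
  out <- stats::setNames(rep("", length(means)), names(means))
  for (s in seq_along(sets)) {
    for (g in sets[[s]]) out[g] <- paste0(out[g], letters[s])
  }
  out
}
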