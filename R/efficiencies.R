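#' Derive efficiency channels from raw gas-exchange columns
#'
#' Adds the four derived efficiency channels to a dataset, each computed
#' row-wise from the raw columns:
#' * `lue` — light-use efficiency `pn / i`, mol CO2 mol^-1 photons
#'   (undefined in darkness: `NA` at `i = 0`);
#' * `ce` — carboxylation efficiency `pn / ci`, mol m^-2 s^-1;
#' * `wue_i` — intrinsic water-use efficiency `pn / gs`, umol CO2 mol^-1
#'   H2O;
#' * `wue_inst` — instantaneous water-use efficiency `pn / tr`, umol CO2
#'   mmol^-1 H2O.
#' A missing source column skips that channel with a warning; division by
#' zero yields `NA` for the affected rows (flagged, not an error).
#'
#' @param dataset An `lrc_dataset` with a `pn` column.
#' @return The dataset with the derivable efficiency columns added.
#' @export
derive_channels <- function(dataset) {
  if (is.data.frame(dataset)) dataset <- light_response_dataset(dataset)
  require_channel(dataset, "pn")
  d <- dataset$data
  safe_ratio <- function(num, den) {
    out <- ifelse(is.finite(den) & den != 0, num / den, NA_real_)
    if (anyNA(out[is.finite(num)])) {
      warning("zero or missing denominator produced NA efficiency values",
              call. = FALSE)
    }
    out
  }
  d$lue <- ifelse(d$i > 0, d$pn / d$i, NA_real_)
  for (ch in list(c("ce", "ci"), c("wue_i", "gs"), c("wue_inst", "tr"))) {
    if (ch[2] %in% names(d)) {
      d[[ch[1]]] <- safe_ratio(d$pn, d[[ch[2]]])
    } else {
      warning("source column `", ch[2], "` missing; channel `", ch[1],
              "` not derived", call. = FALSE)
    }
  }
  dataset$data <- d
  dataset
}

#' Fit the light response of an efficiency or photoprotection channel
#'
#' Fits the channel-appropriate member of the mechanistic family and
#' extracts its maximum and saturation irradiance:
#' * `npq`, `ce`, `wue_i`, `wue_inst` — rising-saturating form
#'   `a*(1 - beta*I)*I / (1 + gamma*I) - c` (intercept `c` fixed at 0 for
#'   `npq`, which is 0 in darkness by definition; free for the others,
#'   which can be negative at low light because net assimilation is).
#'   Maximum and saturation irradiance from the closed forms of
#'   [ye_max()]/[ye_sat_irradiance()] (numeric argmax when `beta = 0`,
#'   where no finite saturation exists).
#' * `phipsii` — monotonically decreasing form
#'   `phi_max*(1 - beta*I)/(1 + gamma*I)`; its maximum is `phi_max`, the
#'   dark value, with no saturation irradiance.
#' * `lue` — not refitted: the net assimilation (`pn`) fit divided by
#'   irradiance, with the peak location from the [lue_saturation()]
#'   closed form.
#' These derivative forms are reconstructions chosen to reproduce the
#' trait structure of efficiency light responses (finite maximum plus
#' saturation irradiance; nonzero dark PSII efficiency); channels are
#' fitted per replicate and trait values averaged.
#'
#' @param dataset An `lrc_dataset`; [derive_channels()] is applied
#'   automatically when the channel is missing but derivable.
#' @param channel One of `"npq"`, `"phipsii"`, `"lue"`, `"ce"`,
#'   `"wue_i"`, `"wue_inst"`.
#' @param mode `"per_replicate"` or `"pooled"`.
#' @param max_iter Iteration cap per fit.
#' @return Class `"lrc_efficiency_fit"`: list with `channel`,
#'   `per_replicate` (data.frame of parameters and traits), `mean` and
#'   `se` of the traits (`max` and `i_sat`), `r_squared`, `mae`,
#'   `converged`.
#' @export
fit_efficiency <- function(dataset, channel, mode = "per_replicate",
                           max_iter = 1000) {
  if (is.data.frame(dataset)) dataset <- light_response_dataset(dataset)
  channel <- match.arg(channel,
                       c("npq", "phipsii", "lue", "ce", "wue_i", "wue_inst"))
  if (!channel %in% names(dataset$data) && channel != "phipsii") {
    dataset <- suppressWarnings(derive_channels(dataset))
  }
  if (channel == "lue") return(fit_lue(dataset, mode))
  require_channel(dataset, channel)
  d <- dataset$data[is.finite(dataset$data[[channel]]), ]
  intercept <- channel %in% c("ce", "wue_i", "wue_inst")
  groups <- if (mode == "per_replicate") split(d, d$replicate) else list(all = d)
  per <- do.call(rbind, lapply(groups, function(g) {
    if (channel == "phipsii") {
      fit_phipsii_one(g$i, g[[channel]], max_iter)
    } else {
      fit_rising_one(g$i, g[[channel]], intercept, max_iter)
    }
  }))
  row.names(per) <- NULL
  num <- per[, c("max", "i_sat")]
  structure(list(
    channel = channel,
    per_replicate = per,
    mean = colMeans(num, na.rm = TRUE),
    se = apply(num, 2, function(v) {
      v <- v[is.finite(v)]
      if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
    }),
    r_squared = mean(per$r_squared),
    mae = mean(per$mae),
    converged = all(per$converged)
  ), class = "lrc_efficiency_fit")
}

fit_rising_one <- function(i, y, intercept, max_iter) {
  # starts as for the mechanistic family, on the gross (intercept-shifted) data
  c0 <- if (intercept && any(i == 0)) max(0, -mean(y[i == 0])) else 0
  gross <- y + c0
  steps <- sort(unique(i[i > 0]))
  low <- i %in% utils::head(steps, 3)
  a0 <- max(1e-8, sum(gross[low] * i[low]) / sum(i[low]^2))
  ymax <- max(gross); isat0 <- max(i[which.max(gross)], 1)
  bg <- tryCatch({
    p <- invert_ye(a0, max(ymax, 1e-8), isat0)
    c(p$beta, p$gamma)
  }, error = function(e) c(1e-4, 1e-3))
  par0 <- c(a0, bg, if (intercept) c0)
  lower <- c(1e-10, 0, 1e-8, if (intercept) -50)
  upper <- c(10, 1e-2, 1, if (intercept) 100)
  pred <- function(par) par[1] * (1 - par[2] * i) / (1 + par[3] * i) * i -
    (if (intercept) par[4] else 0)
  out <- minpack.lm::nls.lm(par = pmin(pmax(par0, lower), upper),
                            lower = lower, upper = upper,
                            fn = function(par) y - pred(par),
                            control = minpack.lm::nls.lm.control(maxiter = max_iter))
  par <- out$par
  # a down-regulation coefficient at numerical zero means a monotone
  # saturating channel with no finite saturation irradiance
  if (par[2] < 1e-8) par[2] <- 0
  off <- if (intercept) par[4] else 0
  if (par[2] > 0) {
    gross_max <- par[1] * ((sqrt(par[2] + par[3]) - sqrt(par[2])) / par[3])^2
    mx <- gross_max - off
    isat <- (sqrt((par[2] + par[3]) / par[2]) - 1) / par[3]
  } else {
    mx <- par[1] / par[3] - off
    isat <- NA_real_
  }
  gof <- goodness_of_fit(y, pred(par), length(par))
  data.frame(alpha = par[1], beta = par[2], gamma = par[3],
             intercept = off, max = mx, i_sat = isat,
             r_squared = gof$r_squared, mae = gof$mae,
             converged = out$info %in% 1:4)
}

fit_phipsii_one <- function(i, y, max_iter) {
  phi0 <- if (any(i == 0)) mean(y[i == 0]) else max(y)
  par0 <- c(phi0, 1e-4, 1e-3)
  lower <- c(1e-4, 0, 1e-8)
  upper <- c(1, 1e-2, 1)
  pred <- function(par) par[1] * (1 - par[2] * i) / (1 + par[3] * i)
  out <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = function(par) y - pred(par),
                            control = minpack.lm::nls.lm.control(maxiter = max_iter))
  par <- out$par
  gof <- goodness_of_fit(y, pred(par), 3)
  data.frame(alpha = par[1], beta = par[2], gamma = par[3], intercept = 0,
             max = par[1], i_sat = NA_real_,
             r_squared = gof$r_squared, mae = gof$mae,
             converged = out$info %in% 1:4)
}

fit_lue <- function(dataset, mode) {
  fit <- fit_curve(dataset, "ye", "pn", mode = mode)
  d <- dataset$data[is.finite(dataset$data$pn) & dataset$data$i > 0, ]
  per <- do.call(rbind, lapply(seq_along(fit$replicate_params), function(r) {
    p <- fit$replicate_params[[r]]
    isat <- tryCatch(lue_saturation(p), error = function(e) NA_real_)
    mx <- if (is.finite(isat)) ye_response(isat, p) / isat else NA_real_
    data.frame(alpha = p$alpha, beta = p$beta, gamma = p$gamma,
               intercept = p$offset, max = mx, i_sat = isat)
  }))
  pred <- ye_response(d$i, fit$params) / d$i
  gof <- goodness_of_fit(d$pn / d$i, pred, fit$k_params)
  num <- per[, c("max", "i_sat")]
  structure(list(
    channel = "lue", per_replicate = per,
    mean = colMeans(num, na.rm = TRUE),
    se = apply(num, 2, function(v) {
      v <- v[is.finite(v)]
      if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
    }),
    r_squared = gof$r_squared, mae = gof$mae, converged = fit$converged,
    pn_fit = fit
  ), class = "lrc_efficiency_fit")
}

#' Irradiance of maximum light-use efficiency
#'
#' Light-use efficiency `LUE(I) = P_n(I)/I` of the mechanistic family
#' peaks where `R_d / I^2 = alpha*(beta + gamma) / (1 + gamma*I)^2`,
#' giving the closed-form root
#' `1/I = sqrt(alpha*(beta + gamma)/R_d) - gamma`. A positive dark
#' respiration is required: with `R_d = 0` LUE is maximal as `I -> 0`
#' (where it approaches `alpha`), and the function returns 0 with the
#' same interpretation. A non-positive root means LUE is monotone over
#' positive irradiance and `NA` is returned.
#'
#' @param pn_params A [ye_params()] object for the net assimilation
#'   channel (its `offset` is the dark respiration).
#' @return Irradiance of peak LUE, umol photons m^-2 s^-1.
#' @examples
#' lue_saturation(invert_ye(0.0528, 24.64, 2520.41, offset = 3.46))
#' @export
lue_saturation <- function(pn_params) {
  stopifnot(inherits(pn_params, "ye_params"))
  p <- pn_params
  if (p$offset == 0) return(0)
  inv <- sqrt(p$alpha * (p$beta + p$gamma) / p$offset) - p$gamma
  if (inv <= 0) return(NA_real_)
  1 / inv
}

#' @export
print.lrc_efficiency_fit <- function(x, ...) {
  cat(sprintf("Efficiency-channel fit: `%s` (%d replicate fits)\n",
              x$channel, nrow(x$per_replicate)))
  cat(sprintf("  max   = %s +/- %s\n", signif(x$mean[["max"]], 4),
              signif(x$se[["max"]], 3)))
  if (is.finite(x$mean[["i_sat"]])) {
    cat(sprintf("  i_sat = %s +/- %s\n", signif(x$mean[["i_sat"]], 5),
                signif(x$se[["i_sat"]], 3)))
  }
  cat(sprintf("  R^2 = %.4f  MAE = %.4g  converged: %s\n",
              x$r_squared, x$mae, x$converged))
  invisible(x)
}
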