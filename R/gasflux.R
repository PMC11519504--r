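#' Fraction of respired CO2 derived from soil inorganic carbon
#'
#' Two end-member linear mixing on delta-13C values. In carbonate-rich soils
#' part of the CO2 release stems from abiotic dissolution of soil inorganic
#' carbon (SIC) rather than microbial respiration of soil organic carbon
#' (SOC). With the del13C of emitted CO2 and of the two end-members,
#' `fSIC = (d13C_CO2 - d13C_SOC) / (d13C_SIC - d13C_SOC)`.
#'
#' Values outside \[0, 1\] (possible under measurement error or end-member
#' misspecification) are returned as-is, never clamped; flagging happens in
#' [partition_respiration()].
#'
#' @param d13c_co2 del13C of the emitted CO2, in permil.
#' @param d13c_soc del13C of soil organic carbon, in permil.
#' @param d13c_sic del13C of soil inorganic carbon, in permil.
#' @return Fraction(s) of CO2 attributable to inorganic carbon.
#' @examples
#' fsic(-15, -25, 0) # 0.4
#' @export
fsic <- function(d13c_co2, d13c_soc, d13c_sic) {
  stopifnot(is.numeric(d13c_co2), is.numeric(d13c_soc), is.numeric(d13c_sic))
  if (any(d13c_sic == d13c_soc, na.rm = TRUE)) {
    abort("d13c_sic must differ from d13c_soc; mixing model undefined")
  }
  (d13c_co2 - d13c_soc) / (d13c_sic - d13c_soc)
}

#' Partition a total CO2 flux into organic and inorganic sources
#'
#' Applies [fsic()] per measurement and splits the total CO2 release rate:
#' `inorganic = total * fSIC`, `organic = total * (1 - fSIC)`. The two parts
#' sum to the total exactly. Rows with fSIC outside \[0, 1\] are flagged in
#' `f_sic_out_of_range`.
#'
#' @param data Data frame with columns `total_co2_rate` (e.g. ng C/g/h),
#'   `d13c_co2`, `d13c_soc`, `d13c_sic`.
#' @return The input as a tibble with `f_sic`, `f_sic_out_of_range`,
#'   `organic_rate`, `inorganic_rate` appended.
#' @examples
#' partition_respiration(tibble::tibble(
#'   total_co2_rate = 100, d13c_co2 = -15, d13c_soc = -25, d13c_sic = 0
#' ))
#' @export
partition_respiration <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("total_co2_rate", "d13c_co2", "d13c_soc", "d13c_sic")
  if (!all(need %in% names(data))) {
    abort(paste("data must have columns", paste(need, collapse = ", ")))
  }
  if (any(data$total_co2_rate < 0, na.rm = TRUE)) {
    abort("total_co2_rate must be non-negative")
  }
  dplyr::mutate(
    tibble::as_tibble(data),
    f_sic = fsic(.data$d13c_co2, .data$d13c_soc, .data$d13c_sic),
    f_sic_out_of_range = .data$f_sic < 0 | .data$f_sic > 1,
    inorganic_rate = .data$total_co2_rate * .data$f_sic,
    organic_rate = .data$total_co2_rate - .data$inorganic_rate
  )
}

#' Forward model for headspace H2 under first-order uptake
#'
#' High-affinity hydrogenase-bearing soil communities draw headspace H2 down
#' toward the atmospheric mixing ratio following first-order kinetics:
#' `C(t) = C_atm + (C0 - C_atm) * exp(-k t)`.
#'
#' @param times_h Times in hours.
#' @param k First-order rate constant, per hour (>= 0).
#' @param c0 Initial mixing ratio, ppmv.
#' @param c_atm Atmospheric asymptote, ppmv (default 0.53).
#' @return Mixing ratios in ppmv at `times_h`.
#' @examples
#' predict_h2(0:12, k = 0.38, c0 = 4)
#' @export
predict_h2 <- function(times_h, k, c0, c_atm = 0.53) {
  stopifnot(is.numeric(times_h), is.numeric(k), k >= 0, is.numeric(c0))
  c_atm + (c0 - c_atm) * exp(-k * times_h)
}

#' Fit a first-order H2 uptake rate constant to a headspace series
#'
#' Estimates the rate constant `k` (per hour) of exponential H2 drawdown
#' toward a fixed atmospheric asymptote, `C(t) = C_atm + (C0 - C_atm)
#' exp(-k t)`. Two routes:
#'
#' * `method = "nls"` (default): nonlinear least squares on the raw mixing
#'   ratios with `C0` and `k` free and `C_atm` fixed, via
#'   [minpack.lm::nlsLM()], started from the log-linear estimates.
#' * `method = "loglinear"`: ordinary regression of `log(C - C_atm)` on
#'   time; only points above `C_atm` and at or above the quantitation limit
#'   `loq` enter the fit.
#'
#' `C_atm` is fixed rather than fitted because headspace series of
#' atmospheric-H2 oxidizers do not draw down below the atmospheric level, so
#' the data carry no information on a free asymptote.
#'
#' @param series Data frame with strictly increasing `time_h` and
#'   non-negative `h2_ppmv`; at least 3 points.
#' @param c_atm Fixed atmospheric asymptote, ppmv (default 0.53).
#' @param method `"nls"` or `"loglinear"`.
#' @param loq Limit of quantitation in ppmv (default 0.12); values below it
#'   are excluded from log-linear fits.
#' @return An object of class `h2_fit`: coefficients `k` (per hour) and
#'   `c0` (ppmv), the fixed `c_atm`, residual summary and the input data.
#'   Methods: [tidy()], [glance()], [autoplot()], `predict()`.
#' @examples
#' s <- gen_h2_series(k = 0.38, times_h = seq(0, 12, length.out = 10),
#'                    noise_sd = 0.05, seed = 1)
#' glance(fit_h2_rate_constant(s))
#' @export
fit_h2_rate_constant <- function(series,
                                 c_atm = 0.53,
                                 method = c("nls", "loglinear"),
                                 loq = 0.12) {
  method <- match.arg(method)
  stopifnot(is.data.frame(series))
  if (!all(c("time_h", "h2_ppmv") %in% names(series))) {
    abort("series must have columns time_h and h2_ppmv")
  }
  t <- series$time_h
  y <- series$h2_ppmv
  if (length(t) < 3L) abort("need at least 3 time points")
  if (any(diff(t) <= 0)) abort("time_h must be strictly increasing")
  if (any(y < 0)) abort("h2_ppmv must be non-negative")
  if (!any(y > c_atm)) {
    abort("no points above the atmospheric level: no consumption signal to fit")
  }

  # Log-linear route doubles as the nls starting-value heuristic.
  keep <- y > c_atm & y >= loq
  if (sum(keep) < 2L) abort("fewer than 2 quantifiable points above c_atm")
  ll <- lm(log(y[keep] - c_atm) ~ t[keep])
  k_ll <- max(-unname(coef(ll)[2]), 0)
  c0_ll <- c_atm + exp(unname(coef(ll)[1]))

  if (method == "loglinear") {
    k_hat <- k_ll
    c0_hat <- c0_ll
    fitted <- predict_h2(t, k_hat, c0_hat, c_atm)
    n_used <- sum(keep)
    converged <- TRUE
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        h2_ppmv ~ c_atm + (c0 - c_atm) * exp(-k * time_h),
        data = data.frame(time_h = t, h2_ppmv = y),
        start = list(c0 = c0_ll, k = max(k_ll, 1e-6)),
        lower = c(c0 = 0, k = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) {
        abort(paste0(
          "nonlinear fit did not converge (", conditionMessage(e),
          "); log-linear starts were k=", signif(k_ll, 4),
          ", c0=", signif(c0_ll, 4)
        ))
      }
    )
    cf <- coef(fit)
    k_hat <- unname(cf["k"])
    c0_hat <- unname(cf["c0"])
    fitted <- predict_h2(t, k_hat, c0_hat, c_atm)
    n_used <- length(t)
    converged <- fit$convInfo$isConv %||% TRUE
  }

  resid <- y - fitted
  structure(
    list(
      k_per_h = k_hat,
      c0_ppmv = c0_hat,
      c_atm_ppmv = c_atm,
      method = method,
      n_points = length(t),
      n_used = n_used,
      residuals = resid,
      sigma = sqrt(sum(resid^2) / max(length(t) - 2, 1)),
      converged = converged,
      data = tibble::as_tibble(series)
    ),
    class = "h2_fit"
  )
}

#' @export
print.h2_fit <- function(x, ...) {
  cat("First-order H2 uptake fit (", x$method, "), C_atm fixed at ",
      x$c_atm_ppmv, " ppmv\n", sep = "")
  cat(sprintf(
    "  k = %.4g per h, C0 = %.4g ppmv, residual sigma = %.3g ppmv (n = %d)\n",
    x$k_per_h, x$c0_ppmv, x$sigma, x$n_points
  ))
  invisible(x)
}

#' @rdname fit_h2_rate_constant
#' @param x An `h2_fit` object.
#' @param ... Unused.
#' @export
tidy.h2_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k", "c0"),
    estimate = c(x$k_per_h, x$c0_ppmv),
    unit = c("per hour", "ppmv")
  )
}

#' @rdname fit_h2_rate_constant
#' @export
glance.h2_fit <- function(x, ...) {
  tibble::tibble(
    k_per_h = x$k_per_h,
    c0_ppmv = x$c0_ppmv,
    c_atm_ppmv = x$c_atm_ppmv,
    sigma = x$sigma,
    n_points = x$n_points,
    n_used = x$n_used,
    method = x$method,
    converged = x$converged
  )
}

#' @export
predict.h2_fit <- function(object, times_h = NULL, ...) {
  times_h <- times_h %||% object$data$time_h
  predict_h2(times_h, object$k_per_h, object$c0_ppmv, object$c_atm_ppmv)
}

#' @rdname fit_h2_rate_constant
#' @param object An `h2_fit` object.
#' @export
autoplot.h2_fit <- function(object, ...) {
  grid <- tibble::tibble(
    time_h = seq(min(object$data$time_h), max(object$data$time_h),
                 length.out = 200)
  )
  grid$h2_ppmv <- predict(object, grid$time_h)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time_h, .data$h2_ppmv)) +
    ggplot2::geom_line(data = grid, color = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$c_atm_ppmv, linetype = "dotted") +
    ggplot2::labs(
      x = "time since sealing (h)", y = expression(H[2] ~ "(ppmv)"),
      title = sprintf("First-order uptake, k = %.3g per h", object$k_per_h)
    ) +
    ggplot2::theme_minimal()
}
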