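#' Biomass generation rates from cellular 2H enrichment
#'
#' Inverts the heavy-water labeling model to estimate the per-cell biomass
#' generation rate. For a cell with measured 2H content `F` (at%), control
#' baseline `F_ctrl`, label water content `F_D2O`, unlabeled water content
#' `F_H2O` and incubation time `t` (hours), the rate is
#'
#' \deqn{\bar\mu = -\ln\!\left(1 - \frac{k (F - F_{ctrl})}{a_w F_{D2O} - F_{H2O}}\right) / t}
#'
#' with the scenario constants `k` (preparation-dilution correction) and
#' `a_w` (water hydrogen assimilation). The rate combines growth and
#' regeneration of cellular material, which heavy-water labeling cannot
#' distinguish; downstream, [replication_time()] converts it to a doubling
#' time under either reading.
#'
#' Cells at or below the baseline get `mu_bar_per_h = 0` with
#' `below_baseline = TRUE`. Cells whose enrichment saturates the model
#' (log argument <= 0, i.e. `k * (F - F_ctrl)` at or beyond the labeling
#' asymptote) get `mu_bar_per_h = NA` with `saturated = TRUE`; they are
#' flagged, never clipped to a finite rate.
#'
#' The control baseline is resolved in this order: `config$f_ctrl_override`
#' if set, else the measured dead-control mean if `control` is supplied,
#' else natural abundance (`config$f_h2o`).
#'
#' @param cells Data frame with `f_at_percent` (add via [isotope_fraction()])
#'   and, unless `t_incub_h` is given, a `timepoint_h` column holding each
#'   cell's incubation time in hours.
#' @param control Optional dead-control summary or raw control table.
#' @param scenarios Physiology scenario table ([physiology_scenarios()] by
#'   default; any tibble with `scenario`, `k_corr`, `a_w` rows). Each cell is
#'   evaluated under every scenario (long output).
#' @param config An [incubation_config()].
#' @param t_incub_h Optional incubation time in hours (scalar or per-cell),
#'   overriding `cells$timepoint_h`.
#' @param mode Replication-time reading passed to [replication_time()] for
#'   the convenience column `tau_days`.
#' @return A tibble with one row per cell x scenario: input columns plus
#'   `scenario`, `k_corr`, `a_w`, `mu_bar_per_h`, `tau_days`,
#'   `below_baseline`, `saturated`.
#' @examples
#' cells <- tibble::tibble(timepoint_h = 24, f_at_percent = 0.60,
#'                         sigma_at_percent = 0.01)
#' biomass_generation_rate(cells)
#' @export
biomass_generation_rate <- function(cells,
                                    control = NULL,
                                    scenarios = physiology_scenarios(),
                                    config = incubation_config(),
                                    t_incub_h = NULL,
                                    mode = c("growth", "regeneration")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(cells), inherits(config, "incubation_config"))
  if (!"f_at_percent" %in% names(cells)) {
    cells <- isotope_fraction(cells)
  }
  if (is.null(t_incub_h)) {
    if (!"timepoint_h" %in% names(cells)) {
      abort("supply t_incub_h or a timepoint_h column")
    }
    t_incub_h <- cells$timepoint_h
  }
  if (any(t_incub_h <= 0, na.rm = TRUE)) abort("incubation time must be > 0 h")
  stopifnot(
    is.data.frame(scenarios),
    all(c("scenario", "k_corr", "a_w") %in% names(scenarios))
  )

  baseline_at <- resolve_baseline(config, control)
  cells <- dplyr::mutate(tibble::as_tibble(cells), .t_incub_h = t_incub_h)

  out <- tidyr::expand_grid(cells, scenarios)
  f_frac <- at_percent_to_fraction(out$f_at_percent)
  fc <- at_percent_to_fraction(baseline_at)
  fd <- at_percent_to_fraction(config$f_d2o)
  fh <- at_percent_to_fraction(config$f_h2o)

  denom <- out$a_w * fd - fh
  if (any(denom <= 0)) {
    abort("a_w * f_d2o - f_h2o must be positive for every scenario")
  }
  log_arg <- 1 - out$k_corr * (f_frac - fc) / denom
  below <- f_frac <= fc
  saturated <- !below & log_arg <= 0
  mu <- -log(pmax(log_arg, .Machine$double.xmin)) / out$.t_incub_h
  mu[below] <- 0
  mu[saturated] <- NA_real_

  out <- dplyr::mutate(
    out,
    baseline_at_percent = baseline_at,
    mu_bar_per_h = mu,
    tau_days = replication_time(mu, mode = mode),
    below_baseline = below,
    saturated = saturated
  )
  dplyr::rename(out, t_incub_h = ".t_incub_h")
}

resolve_baseline <- function(config, control = NULL) {
  if (!is.null(config$f_ctrl_override)) {
    return(config$f_ctrl_override)
  }
  if (!is.null(control)) {
    return(as_control_summary(control)$mean_at_percent)
  }
  config$f_h2o
}

#' Forward enrichment model: expected 2H content for a given rate
#'
#' Algebraic inverse of [biomass_generation_rate()]: the 2H atom fraction a
#' cell growing at rate `mu_bar_per_h` reaches after `t_incub_h` hours in
#' label water,
#' `F = F_ctrl + (a_w * F_D2O - F_H2O) * (1 - exp(-mu * t)) / k`.
#' Used as the forward model by the synthetic-cohort generator and for
#' round-trip checks.
#'
#' @param mu_bar_per_h Biomass generation rate(s), per hour (>= 0).
#' @param scenario One-row scenario tibble ([physiology_scenario()]).
#' @param config An [incubation_config()].
#' @param t_incub_h Incubation time in hours.
#' @param baseline_at_percent Control baseline in at%; defaults to the
#'   config override if set, else natural abundance.
#' @return Expected 2H content in at%.
#' @examples
#' invert_enrichment(0.00522, physiology_scenario("heterotroph"),
#'                   t_incub_h = 24)
#' @export
invert_enrichment <- function(mu_bar_per_h,
                              scenario,
                              config = incubation_config(),
                              t_incub_h,
                              baseline_at_percent = NULL) {
  stopifnot(is.data.frame(scenario), nrow(scenario) == 1L,
            inherits(config, "incubation_config"))
  if (any(mu_bar_per_h < 0, na.rm = TRUE)) abort("mu_bar_per_h must be >= 0")
  baseline_at <- baseline_at_percent %||% resolve_baseline(config)
  fc <- at_percent_to_fraction(baseline_at)
  fd <- at_percent_to_fraction(config$f_d2o)
  fh <- at_percent_to_fraction(config$f_h2o)
  f <- fc + (scenario$a_w * fd - fh) * (1 - exp(-mu_bar_per_h * t_incub_h)) / scenario$k_corr
  fraction_to_at_percent(f)
}

#' Replication time from a biomass generation rate
#'
#' Converts a biomass generation rate (per hour) to the time needed to
#' double the amount of biomass, in days. If the rate is read as exponential
#' growth (cell numbers increase), `tau = ln(2) / mu`; if read as pure
#' regeneration (turnover of cellular material at constant cell number),
#' `tau = 1 / mu`. The default ascribes rates entirely to growth.
#'
#' @param mu_bar_per_h Biomass generation rate(s), per hour.
#' @param mode `"growth"` (default) or `"regeneration"`.
#' @return Replication time(s) in days; `Inf` for a zero or negative rate,
#'   `NA` for missing rates (e.g. saturated cells).
#' @examples
#' replication_time(log(2) / 24) # 1 day
#' @export
replication_time <- function(mu_bar_per_h, mode = c("growth", "regeneration")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(mu_bar_per_h))
  numer <- if (mode == "growth") log(2) else 1
  tau_h <- ifelse(mu_bar_per_h > 0, numer / mu_bar_per_h, Inf)
  tau_h[is.na(mu_bar_per_h)] <- NA_real_
  tau_h / 24
}

#' Per-time-point cohort summary of activity and replication times
#'
#' Runs the full single-cell pipeline (activity classification, growth
#' inference) and summarizes each time point under each physiology scenario:
#' number of cells measured and active, active fraction, median 2H content of
#' all cells, median/min/max replication time of the active cells, and the
#' fraction of cells able to divide within each of the supplied day
#' thresholds.
#'
#' The divide-within fractions use all measured cells of the time point as
#' denominator by default (an "at most x% of cells could double" reading);
#' set `denominator = "active"` to restrict to active cells.
#'
#' @param cells Data frame of measured cells (`h1_counts`/`h2_counts` or
#'   precomputed `f_at_percent`/`sigma_at_percent`) with `timepoint_h`.
#' @param control Dead-control summary or raw control table.
#' @param scenarios Scenario table; default both built-ins.
#' @param config An [incubation_config()].
#' @param divide_days Numeric day thresholds for the divide-within fractions
#'   (default `c(1, 2, 3)`).
#' @param denominator `"all"` (default) or `"active"`.
#' @param mode Replication-time reading, see [replication_time()].
#' @return A tibble with one row per `timepoint_h` x scenario and columns
#'   `n_measured`, `n_active`, `frac_active`, `median_f_at_percent`,
#'   `median_tau_days`, `min_tau_days`, `max_tau_days`, `n_saturated` and one
#'   `frac_divide_within_<d>d` column per threshold.
#' @examples
#' sim <- gen_cell_cohort(cell_cohort_spec(n_cells = 40), seed = 1)
#' ctrl <- gen_dead_control(cell_cohort_spec(), seed = 2)
#' cohort_summary(sim$roi, ctrl)
#' @export
cohort_summary <- function(cells,
                           control,
                           scenarios = physiology_scenarios(),
                           config = incubation_config(),
                           divide_days = c(1, 2, 3),
                           denominator = c("all", "active"),
                           mode = c("growth", "regeneration")) {
  denominator <- match.arg(denominator)
  mode <- match.arg(mode)
  stopifnot(is.data.frame(cells))
  if (nrow(cells) == 0L) abort("no cells supplied")
  if (!"timepoint_h" %in% names(cells)) abort("cells must carry timepoint_h")
  if (!all(c("f_at_percent", "sigma_at_percent") %in% names(cells))) {
    cells <- isotope_fraction(cells)
  }
  ctrl <- as_control_summary(control)
  classified <- classify_active(cells, ctrl)
  rates <- biomass_generation_rate(
    classified,
    control = ctrl, scenarios = scenarios, config = config, mode = mode
  )

  per_cell_div <- function(tau, active, d) {
    denom_n <- if (denominator == "all") length(tau) else sum(active)
    if (denom_n == 0L) return(NA_real_)
    sum(!is.na(tau) & tau <= d) / denom_n
  }

  summ <- rates |>
    dplyr::group_by(.data$timepoint_h, .data$scenario) |>
    dplyr::summarise(
      n_measured = dplyr::n(),
      n_active = sum(.data$active),
      frac_active = .data$n_active / .data$n_measured,
      median_f_at_percent = median(.data$f_at_percent),
      median_tau_days = safe_median(.data$tau_days[.data$active]),
      min_tau_days = safe_min(.data$tau_days[.data$active]),
      max_tau_days = safe_max(.data$tau_days[.data$active]),
      n_saturated = sum(.data$saturated),
      divide = list(
        setNames(
          vapply(divide_days, function(d) {
            per_cell_div(.data$tau_days, .data$active, d)
          }, numeric(1)),
          paste0("frac_divide_within_", divide_days, "d")
        )
      ),
      .groups = "drop"
    )
  tidyr::unnest_wider(summ, "divide")
}

safe_median <- function(x) {
  x <- x[!is.na(x) & is.finite(x)]
  if (length(x) == 0L) NA_real_ else median(x)
}
safe_min <- function(x) {
  x <- x[!is.na(x) & is.finite(x)]
  if (length(x) == 0L) NA_real_ else min(x)
}
safe_max <- function(x) {
  x <- x[!is.na(x) & is.finite(x)]
  if (length(x) == 0L) NA_real_ else max(x)
}
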