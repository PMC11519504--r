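#' Correct a secondary-ion count rate for detector dead time
#'
#' Electron multipliers undercount at high rates because ions arriving within
#' the dead time of a previous event are lost. Under the non-paralyzable
#' model the true rate `n` relates to the measured rate `m` by
#' `n = m / (1 - m * tau_d)`, with `tau_d` the dead time.
#'
#' Exported per-ROI count tables are normally already dead-time corrected by
#' the instrument software; apply this only to raw count rates.
#'
#' @param rate_cps Measured count rate(s), counts per second (>= 0).
#' @param dead_time_ns Detector dead time in nanoseconds (default 44).
#' @return Corrected count rate(s), counts per second; always >= `rate_cps`.
#' @examples
#' dead_time_correct(1e6) # ~4.6% correction at 1 Mcps
#' @export
dead_time_correct <- function(rate_cps, dead_time_ns = 44) {
  stopifnot(is.numeric(rate_cps), is.numeric(dead_time_ns), dead_time_ns >= 0)
  if (any(rate_cps < 0, na.rm = TRUE)) {
    abort("count rates must be non-negative")
  }
  tau_s <- dead_time_ns * 1e-9
  load <- rate_cps * tau_s
  if (any(load >= 1, na.rm = TRUE)) {
    abort(paste0(
      "detector saturated: rate * dead_time >= 1 for ",
      sum(load >= 1, na.rm = TRUE), " value(s); dead-time model undefined"
    ))
  }
  rate_cps / (1 - load)
}

#' Correct per-ROI ion counts for quasi-simultaneous arrival
#'
#' Quasi-simultaneous arrival (QSA) makes electron multipliers register
#' several secondary ions of an abundant species as one event. The default
#' strategy rescales each species' counts by a multiplicative sensitivity
#' factor: 1.06 for C2-, 1.05 for CN- and 1.00 for H-. Because the hydrogen
#' factor is 1.00 and it applies to both isotopologues, the 2H/(1H+2H)
#' isotope fraction is invariant under this correction.
#'
#' Count columns are matched to species by name: `h1_counts` and `h2_counts`
#' use the `h` factor; any other `<species>_counts` column uses the factor of
#' the same name. Species without a configured factor pass through unchanged
#' (factor 1.00).
#'
#' @param roi Data frame of per-ROI counts with `*_counts` columns.
#' @param config An [incubation_config()] carrying `qsa_factors`, or a named
#'   numeric vector of factors.
#' @return A tibble with rescaled count columns; the applied strategy and
#'   factors are recorded in attributes `qsa_strategy` and `qsa_factors`.
#' @examples
#' roi <- tibble::tibble(roi_id = "r1", h1_counts = 1000, h2_counts = 10,
#'                       cn_counts = 1000)
#' qsa_correct(roi)
#' @export
qsa_correct <- function(roi, config = incubation_config()) {
  factors <- if (inherits(config, "incubation_config")) config$qsa_factors else config
  stopifnot(is.data.frame(roi))
  if (length(factors) > 0 && (is.null(names(factors)) || !is.numeric(factors))) {
    abort("QSA factors must be a named numeric vector")
  }
  count_cols <- grep("_counts$", names(roi), value = TRUE)
  out <- tibble::as_tibble(roi)
  for (col in count_cols) {
    if (any(out[[col]] < 0, na.rm = TRUE)) {
      abort(paste0("negative counts in column '", col, "'"))
    }
    species <- sub("_counts$", "", col)
    if (species %in% c("h1", "h2")) species <- "h"
    fac <- if (species %in% names(factors)) unname(factors[[species]]) else 1.0
    out[[col]] <- out[[col]] * fac
  }
  attr(out, "qsa_strategy") <- "multiplicative per-species factor"
  attr(out, "qsa_factors") <- factors
  out
}

#' Poisson counting uncertainty of a 2H atom fraction
#'
#' The analytical uncertainty of the per-ROI isotope fraction
#' `F = 2H / (1H + 2H)`, arising from the random error of single-ion
#' counting, propagates to
#' `sigma = 100 / (h1 + h2)^2 * sqrt(h1^2 * h2 + h1 * h2^2)` in at%.
#'
#' @param h1 Total 1H- counts per ROI (summed over pixels and layers).
#' @param h2 Total 2H- counts per ROI.
#' @return Poisson standard deviation of the atom fraction, in at%.
#' @examples
#' poisson_sigma(10000, 100)
#' @export
poisson_sigma <- function(h1, h2) {
  stopifnot(is.numeric(h1), is.numeric(h2))
  if (any(h1 < 0 | h2 < 0, na.rm = TRUE)) {
    abort("ion counts must be non-negative")
  }
  total <- h1 + h2
  if (any(total <= 0, na.rm = TRUE)) {
    abort("h1 + h2 must be positive for a measurable ROI")
  }
  100 / total^2 * sqrt(h1^2 * h2 + h1 * h2^2)
}

#' Per-ROI 2H atom fraction with Poisson uncertainty
#'
#' Computes the deuterium content of each ROI as the isotope fraction
#' `F = 100 * 2H / (1H + 2H)` in at%, together with its Poisson counting
#' uncertainty from [poisson_sigma()].
#'
#' @param roi Data frame with integer columns `h1_counts` and `h2_counts`
#'   (one row per ROI; counts assumed dead-time and QSA corrected).
#' @return The input as a tibble with columns `f_at_percent` and
#'   `sigma_at_percent` appended.
#' @examples
#' isotope_fraction(tibble::tibble(h1_counts = 9900, h2_counts = 100))
#' @export
isotope_fraction <- function(roi) {
  stopifnot(is.data.frame(roi))
  if (!all(c("h1_counts", "h2_counts") %in% names(roi))) {
    abort("roi must have columns h1_counts and h2_counts")
  }
  h1 <- roi$h1_counts
  h2 <- roi$h2_counts
  if (any(h1 < 0 | h2 < 0, na.rm = TRUE)) abort("ion counts must be non-negative")
  if (any(h1 + h2 <= 0, na.rm = TRUE)) {
    abort("h1_counts + h2_counts must be positive for every ROI")
  }
  dplyr::mutate(
    tibble::as_tibble(roi),
    f_at_percent = 100 * .data$h2_counts / (.data$h1_counts + .data$h2_counts),
    sigma_at_percent = poisson_sigma(.data$h1_counts, .data$h2_counts)
  )
}

#' Summarize the dead-control cell population
#'
#' The activity classification is anchored on a formaldehyde-killed control
#' incubated alongside the labeled samples: its cells carry only the
#' abiotic/background 2H signal. The classifier threshold is the control mean
#' plus three sample standard deviations.
#'
#' @param control Data frame of control cells, either already carrying
#'   `f_at_percent` or raw `h1_counts`/`h2_counts` (then converted via
#'   [isotope_fraction()]).
#' @return A one-row tibble: `mean_at_percent`, `sd_at_percent`, `n_cells`.
#' @examples
#' ctrl <- tibble::tibble(f_at_percent = c(0.020, 0.022, 0.024))
#' summarize_dead_control(ctrl)
#' @export
summarize_dead_control <- function(control) {
  stopifnot(is.data.frame(control))
  if (!"f_at_percent" %in% names(control)) {
    control <- isotope_fraction(control)
  }
  f <- control$f_at_percent
  if (length(f) < 2L) {
    abort("need at least 2 dead-control cells to estimate mean and SD")
  }
  tibble::tibble(
    mean_at_percent = mean(f),
    sd_at_percent = sd(f),
    n_cells = length(f)
  )
}

#' Classify cells as anabolically active
#'
#' A cell is called active only if both criteria hold: (1) its 2H content
#' exceeds the dead-control mean plus three control standard deviations, and
#' (2) its enrichment over the control mean exceeds three times its own
#' Poisson counting uncertainty. The simultaneous application of both
#' criteria corresponds to a confidence level of 99.86% (p < 0.00135).
#'
#' @param cells Data frame of measured cells with `f_at_percent` and
#'   `sigma_at_percent` (add them with [isotope_fraction()] if absent).
#' @param control Dead-control summary from [summarize_dead_control()], or a
#'   raw control cell table (summarized on the fly).
#' @return `cells` as a tibble with columns `threshold3sd`,
#'   `margin_at_percent`, `three_sigma_poisson`, `exceeds_control`,
#'   `exceeds_poisson` and the combined call `active` appended.
#' @examples
#' cells <- tibble::tibble(h1_counts = c(99400, 99950),
#'                         h2_counts = c(600, 50))
#' ctrl <- tibble::tibble(f_at_percent = c(0.020, 0.022, 0.024, 0.021))
#' classify_active(isotope_fraction(cells), ctrl)
#' @export
classify_active <- function(cells, control) {
  stopifnot(is.data.frame(cells))
  if (!all(c("f_at_percent", "sigma_at_percent") %in% names(cells))) {
    cells <- isotope_fraction(cells)
  }
  ctrl <- as_control_summary(control)
  dplyr::mutate(
    tibble::as_tibble(cells),
    threshold3sd = ctrl$mean_at_percent + 3 * ctrl$sd_at_percent,
    margin_at_percent = .data$f_at_percent - ctrl$mean_at_percent,
    three_sigma_poisson = 3 * .data$sigma_at_percent,
    exceeds_control = .data$f_at_percent > .data$threshold3sd,
    exceeds_poisson = .data$margin_at_percent > .data$three_sigma_poisson,
    active = .data$exceeds_control & .data$exceeds_poisson
  )
}

# Accept either a summary row or a raw control table.
as_control_summary <- function(control) {
  stopifnot(is.data.frame(control))
  if (all(c("mean_at_percent", "sd_at_percent") %in% names(control))) {
    if (nrow(control) != 1L) abort("control summary must be a single row")
    control
  } else {
    summarize_dead_control(control)
  }
}
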