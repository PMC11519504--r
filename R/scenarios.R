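#' Physiology scenarios for the enrichment-to-growth model
#'
#' The mapping from cellular deuterium enrichment to a biomass generation
#' rate depends on two constants: `k_corr`, a correction factor for the
#' dilution of the cellular 2H content during sample preparation, and `a_w`,
#' the water hydrogen assimilation constant (the fraction of biomass hydrogen
#' derived from water, folded together with the isotope fractionation of the
#' incorporating reactions). Both depend on the assumed physiology. Two
#' extreme-case scenarios bracket the metabolic diversity of a biocrust
#' community: obligate heterotrophy (`k_corr = 1.69`, `a_w = 0.28`, most
#' hydrogen from organic substrates) and obligate chemoautotrophy
#' (`k_corr = 1.49`, `a_w = 0.79`, hydrogen from water). Photoautotrophs are
#' conventionally evaluated with the chemoautotrophic constants, which may
#' underestimate their rates.
#'
#' @param name Scenario name. One of the built-ins (`"heterotroph"`,
#'   `"chemoautotroph"`) or any label when `k_corr` and `a_w` are supplied.
#' @param k_corr Dimensionless correction factor (> 0). Overrides the
#'   built-in value when given.
#' @param a_w Dimensionless water hydrogen assimilation constant in (0, 1].
#'
#' @return A one-row tibble with columns `scenario`, `k_corr`, `a_w`
#'   (`physiology_scenario()`), or a two-row tibble of both built-ins
#'   (`physiology_scenarios()`).
#' @examples
#' physiology_scenarios()
#' physiology_scenario("heterotroph")
#' physiology_scenario("mixotroph_guess", k_corr = 1.6, a_w = 0.5)
#' @export
physiology_scenario <- function(name, k_corr = NULL, a_w = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  builtin <- physiology_scenarios()
  if (is.null(k_corr) || is.null(a_w)) {
    hit <- builtin[builtin$scenario == name, ]
    if (nrow(hit) == 0L) {
      abort(paste0(
        "Unknown scenario '", name, "'; built-ins are ",
        paste(builtin$scenario, collapse = ", "),
        ". Supply k_corr and a_w for a custom scenario."
      ))
    }
    k_corr <- k_corr %||% hit$k_corr
    a_w <- a_w %||% hit$a_w
  }
  if (!is.numeric(k_corr) || k_corr <= 0) {
    abort("k_corr must be a positive number")
  }
  if (!is.numeric(a_w) || a_w <= 0 || a_w > 1) {
    abort("a_w must lie in (0, 1]")
  }
  tibble::tibble(scenario = name, k_corr = as.numeric(k_corr), a_w = as.numeric(a_w))
}

#' @rdname physiology_scenario
#' @export
physiology_scenarios <- function() {
  tibble::tibble(
    scenario = c("heterotroph", "chemoautotroph"),
    k_corr = c(1.69, 1.49),
    a_w = c(0.28, 0.79)
  )
}

#' Incubation and instrument configuration for heavy-water labeling
#'
#' Bundles the constants of a heavy-water incubation that enter the
#' enrichment-to-growth model and the per-ROI count corrections.
#'
#' @param f_d2o 2H content of the label water, in at% (default 30, i.e. a
#'   30% v/v heavy-water amendment).
#' @param f_h2o 2H content of unlabeled water, in at% (natural abundance,
#'   default 0.0156).
#' @param f_ctrl_override Optional fixed control baseline in at%. When set it
#'   takes precedence over a measured dead-control mean.
#' @param dead_time_ns Electron-multiplier dead time in nanoseconds used by
#'   [dead_time_correct()] (default 44).
#' @param qsa_factors Named numeric vector of per-species
#'   quasi-simultaneous-arrival sensitivity factors for [qsa_correct()].
#'   Defaults: `c2` (C2-) 1.06, `cn` (CN-) 1.05, `h` (H-) 1.00.
#'
#' @return A list of class `incubation_config`.
#' @examples
#' cfg <- incubation_config()
#' cfg$f_d2o
#' @export
incubation_config <- function(f_d2o = 30,
                              f_h2o = 0.0156,
                              f_ctrl_override = NULL,
                              dead_time_ns = 44,
                              qsa_factors = c(h = 1.00, c2 = 1.06, cn = 1.05)) {
  stopifnot(
    is.numeric(f_d2o), f_d2o > 0, f_d2o <= 100,
    is.numeric(f_h2o), f_h2o >= 0, f_h2o < f_d2o,
    is.numeric(dead_time_ns), dead_time_ns >= 0
  )
  if (!is.null(f_ctrl_override)) {
    stopifnot(is.numeric(f_ctrl_override), f_ctrl_override >= 0)
  }
  if (length(qsa_factors) > 0 && is.null(names(qsa_factors))) {
    abort("qsa_factors must be a named numeric vector (species -> factor)")
  }
  structure(
    list(
      f_d2o = f_d2o,
      f_h2o = f_h2o,
      f_ctrl_override = f_ctrl_override,
      dead_time_ns = dead_time_ns,
      qsa_factors = qsa_factors
    ),
    class = "incubation_config"
  )
}

#' @export
print.incubation_config <- function(x, ...) {
  cat("<incubation_config>\n")
  cat("  label water      :", x$f_d2o, "at% 2H\n")
  cat("  unlabeled water  :", x$f_h2o, "at% 2H\n")
  cat(
    "  control baseline :",
    if (is.null(x$f_ctrl_override)) "measured dead control (or natural abundance)"
    else paste(x$f_ctrl_override, "at% (override)"), "\n"
  )
  cat("  detector dead time:", x$dead_time_ns, "ns\n")
  cat(
    "  QSA factors      :",
    paste(names(x$qsa_factors), x$qsa_factors, sep = "=", collapse = ", "), "\n"
  )
  invisible(x)
}

# at% values are the external currency; the growth model works on fractions.
# Conversion is localized here.
at_percent_to_fraction <- function(x) x / 100
fraction_to_at_percent <- function(x) x * 100
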