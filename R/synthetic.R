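#' Specification of a synthetic single-cell labeling cohort
#'
#' Describes the statistical structure of a heavy-water labeling experiment
#' at the per-cell level: a latent active/inactive state, a lognormal
#' replication-time law for active cells mapped through the forward
#' enrichment model ([invert_enrichment()]) to a true 2H content, and ion
#' counts drawn from the Poisson/binomial counting model. Defaults mirror a
#' rain-pulse experiment: ~240 cells per time point at 3/6/12/24 h, 95% of
#' cells active, replication times lognormal around a median of 5.6 days,
#' total H counts lognormal around 1e6 per ROI, and a natural-abundance
#' baseline of 0.0156 at% with a small abiotic jitter.
#'
#' The replication time (not the rate) is lognormal because cohort
#' replication times are the reported, histogrammed quantity.
#'
#' @param n_cells Cells per time point.
#' @param timepoints_h Sampling times (hours of hydrated incubation).
#' @param p_active Probability that a cell is anabolically active.
#' @param tau_median_days,tau_log_sd Lognormal law of the replication time
#'   (days) of active cells.
#' @param scenario One-row scenario tibble used for the forward map.
#' @param total_counts_median,total_counts_log_sd Lognormal law of the total
#'   hydrogen ion counts per ROI.
#' @param baseline_at_percent Inactive-cell 2H content, at%.
#' @param baseline_jitter_sd Cell-to-cell SD of the baseline, at%.
#' @param n_control Cells in the dead control ([gen_dead_control()]).
#' @param config An [incubation_config()].
#' @return A list of class `cell_cohort_spec`.
#' @export
cell_cohort_spec <- function(n_cells = 240,
                             timepoints_h = c(3, 6, 12, 24),
                             p_active = 0.95,
                             tau_median_days = 5.6,
                             tau_log_sd = 1.1,
                             scenario = physiology_scenario("heterotroph"),
                             total_counts_median = 1e6,
                             total_counts_log_sd = 0.8,
                             baseline_at_percent = 0.0156,
                             baseline_jitter_sd = 0.002,
                             n_control = 178,
                             config = incubation_config()) {
  stopifnot(
    n_cells >= 1, all(timepoints_h > 0),
    p_active >= 0, p_active <= 1,
    tau_median_days > 0, tau_log_sd >= 0,
    total_counts_median > 0, total_counts_log_sd >= 0,
    baseline_at_percent >= 0, baseline_jitter_sd >= 0,
    n_control >= 2,
    inherits(config, "incubation_config")
  )
  structure(
    list(
      n_cells = n_cells, timepoints_h = timepoints_h, p_active = p_active,
      tau_median_days = tau_median_days, tau_log_sd = tau_log_sd,
      scenario = scenario,
      total_counts_median = total_counts_median,
      total_counts_log_sd = total_counts_log_sd,
      baseline_at_percent = baseline_at_percent,
      baseline_jitter_sd = baseline_jitter_sd,
      n_control = n_control,
      config = config
    ),
    class = "cell_cohort_spec"
  )
}

#' Generate a synthetic labeled cell cohort
#'
#' Draws a seeded cohort per the spec: each cell is active with probability
#' `p_active`; active cells draw a replication time from the lognormal law,
#' convert it to a rate (`mu = ln 2 / tau`) and to a true 2H content through
#' the forward enrichment model at their time point; inactive cells sit at
#' the baseline plus jitter. Total hydrogen counts are lognormal and the 2H
#' counts are binomial given the total and the true atom fraction — the
#' conditional form of the Poisson counting model underlying the analytical
#' uncertainty.
#'
#' @param spec A [cell_cohort_spec()].
#' @param seed Integer seed; the output is a pure function of (spec, seed)
#'   and the global RNG state is left untouched.
#' @return A list with `roi` (sample_id, timepoint_h, roi_id, h1_counts,
#'   h2_counts — the analysis input format) and `truth` (latent state, true
#'   replication time and 2H content per cell).
#' @examples
#' sim <- gen_cell_cohort(cell_cohort_spec(n_cells = 10), seed = 1)
#' sim$roi
#' @export
gen_cell_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cell_cohort_spec"))
  withr::with_seed(as.integer(seed), {
    cells <- tidyr::expand_grid(
      timepoint_h = spec$timepoints_h,
      cell = seq_len(spec$n_cells)
    )
    n <- nrow(cells)
    active <- stats::runif(n) < spec$p_active
    tau_days <- rlnorm(n, meanlog = log(spec$tau_median_days),
                       sdlog = spec$tau_log_sd)
    tau_days[!active] <- NA_real_
    mu <- ifelse(active, log(2) / (tau_days * 24), 0)
    f_true <- ifelse(
      active,
      invert_enrichment(
        mu, spec$scenario, spec$config,
        t_incub_h = cells$timepoint_h,
        baseline_at_percent = spec$baseline_at_percent
      ),
      pmax(spec$baseline_at_percent + rnorm(n, 0, spec$baseline_jitter_sd), 0)
    )
    total <- draw_total_counts(n, spec)
    h2 <- rbinom(n, size = total, prob = at_percent_to_fraction(f_true))
    roi <- tibble::tibble(
      sample_id = paste0("t", cells$timepoint_h, "h"),
      timepoint_h = cells$timepoint_h,
      roi_id = paste0("t", cells$timepoint_h, "h_c",
                      formatC(cells$cell, width = 3, flag = "0")),
      h1_counts = total - h2,
      h2_counts = h2
    )
    truth <- tibble::tibble(
      roi_id = roi$roi_id,
      timepoint_h = cells$timepoint_h,
      active_true = active,
      tau_days_true = tau_days,
      mu_bar_per_h_true = mu,
      f_true_at_percent = f_true,
      total_counts = total
    )
    list(roi = roi, truth = truth)
  })
}

#' Generate a synthetic dead-control ROI table
#'
#' Emulates the formaldehyde-killed control: every cell is inactive at the
#' baseline 2H content plus jitter, with the same counting model as
#' [gen_cell_cohort()].
#'
#' @inheritParams gen_cell_cohort
#' @return A tibble in the ROI input format (`sample_id = "control"`).
#' @examples
#' gen_dead_control(cell_cohort_spec(n_control = 5), seed = 1)
#' @export
gen_dead_control <- function(spec, seed) {
  stopifnot(inherits(spec, "cell_cohort_spec"))
  withr::with_seed(as.integer(seed), {
    n <- spec$n_control
    f_true <- pmax(
      spec$baseline_at_percent + rnorm(n, 0, spec$baseline_jitter_sd), 0
    )
    total <- draw_total_counts(n, spec)
    h2 <- rbinom(n, size = total, prob = at_percent_to_fraction(f_true))
    tibble::tibble(
      sample_id = "control",
      timepoint_h = max(spec$timepoints_h),
      roi_id = paste0("ctrl_c", formatC(seq_len(n), width = 3, flag = "0")),
      h1_counts = total - h2,
      h2_counts = h2
    )
  })
}

# rbinom's size is integer-limited; cap totals well below .Machine$integer.max
draw_total_counts <- function(n, spec) {
  total <- round(rlnorm(n, meanlog = log(spec$total_counts_median),
                        sdlog = spec$total_counts_log_sd))
  pmin(pmax(total, 100), 2e9)
}

#' Specification of a synthetic MAG-resolved expression experiment
#'
#' Describes a genome-resolved metatranscriptome with hydration-phase
#' structure: each gene has a base expression level and per-phase
#' (dry/early/main) expression multipliers shared within the community
#' design; each MAG's abundance fluctuates independently per sample with a
#' lognormal multiplier whose log-sd (default 1.0) produces the ~4- to
#' 15-fold replicate-to-replicate swings seen in real crust replicates.
#' Counts are negative binomial around the product of gene base, phase
#' program and MAG abundance, scaled to the sequencing depth.
#'
#' The default layout is desk-scale: 12 MAGs over the 8-time-point x
#' 3-replicate hydration series.
#'
#' @param n_mags Number of MAGs.
#' @param genes_per_mag Length-2 range of genes per MAG (uniform draw).
#' @param gene_length_meanlog,gene_length_sdlog Lognormal law of gene
#'   lengths in bp (floored at 100 bp).
#' @param phase_program_sd Log-scale SD of the per-gene phase multipliers;
#'   0 removes phase structure.
#' @param abundance_log_sd Log-scale SD of the per-sample per-MAG abundance
#'   multiplier; 0 removes abundance fluctuation.
#' @param dispersion Negative-binomial dispersion (variance = mu + mu^2 *
#'   dispersion).
#' @param depth Expected mapped reads per sample.
#' @param timepoints_h Sampling times; must map to phases via
#'   [assign_phase()].
#' @param n_replicates Replicates per time point.
#' @return A list of class `mag_experiment_spec`.
#' @export
mag_experiment_spec <- function(n_mags = 12,
                                genes_per_mag = c(60, 120),
                                gene_length_meanlog = log(900),
                                gene_length_sdlog = 0.35,
                                phase_program_sd = 1.0,
                                abundance_log_sd = 1.0,
                                dispersion = 0.3,
                                depth = 3e5,
                                timepoints_h = c(0, 0.25, 0.5, 3, 6, 12, 39, 55),
                                n_replicates = 3) {
  stopifnot(
    n_mags >= 2, length(genes_per_mag) == 2, all(genes_per_mag >= 1),
    phase_program_sd >= 0, abundance_log_sd >= 0,
    dispersion > 0, depth >= 0, n_replicates >= 1
  )
  assign_phase(timepoints_h) # errors on unknown time points
  structure(
    list(
      n_mags = n_mags, genes_per_mag = genes_per_mag,
      gene_length_meanlog = gene_length_meanlog,
      gene_length_sdlog = gene_length_sdlog,
      phase_program_sd = phase_program_sd,
      abundance_log_sd = abundance_log_sd,
      dispersion = dispersion, depth = depth,
      timepoints_h = timepoints_h, n_replicates = n_replicates
    ),
    class = "mag_experiment_spec"
  )
}

#' Generate a synthetic MAG-structured count experiment
#'
#' @param spec A [mag_experiment_spec()].
#' @param seed Integer seed; output is a pure function of (spec, seed).
#' @return A list: `counts` (gene_id + one column per sample), `gene_info`
#'   (gene_id, mag_id, length_bp), `metadata` (sample_id, timepoint_h,
#'   replicate, water_content, phase) and `truth` (per-gene phase
#'   multipliers and per-sample MAG abundance multipliers).
#' @examples
#' sim <- gen_mag_counts(mag_experiment_spec(n_mags = 3,
#'                       genes_per_mag = c(5, 8)), seed = 1)
#' sim$metadata
#' @export
gen_mag_counts <- function(spec, seed) {
  stopifnot(inherits(spec, "mag_experiment_spec"))
  withr::with_seed(as.integer(seed), {
    mags <- sprintf("mag%02d", seq_len(spec$n_mags))
    n_genes_per <- sample(spec$genes_per_mag[1]:spec$genes_per_mag[2],
                          spec$n_mags, replace = TRUE)
    gene_info <- tibble::tibble(
      mag_id = rep(mags, n_genes_per)
    )
    n_genes <- nrow(gene_info)
    gene_info$gene_id <- sprintf("%s_g%04d", gene_info$mag_id,
                                 unlist(lapply(n_genes_per, seq_len)))
    gene_info$length_bp <- pmax(
      round(rlnorm(n_genes, spec$gene_length_meanlog, spec$gene_length_sdlog)),
      100
    )
    gene_info <- gene_info[, c("gene_id", "mag_id", "length_bp")]

    metadata <- tidyr::expand_grid(
      timepoint_h = spec$timepoints_h,
      replicate = seq_len(spec$n_replicates)
    )
    metadata$phase <- assign_phase(metadata$timepoint_h)
    metadata$sample_id <- sprintf("t%g_r%d", metadata$timepoint_h,
                                  metadata$replicate)
    # plausible water contents per phase: dry < 6%, early ~25%, main 18-24%
    metadata$water_content <- c(dry = 2, early = 25, main = 21)[
      as.character(metadata$phase)
    ] + round(stats::runif(nrow(metadata), -1, 1), 1)
    metadata <- metadata[, c("sample_id", "timepoint_h", "replicate",
                             "water_content", "phase")]

    base <- rlnorm(n_genes, meanlog = 0, sdlog = 1)
    phase_mult <- matrix(
      rlnorm(n_genes * 3, meanlog = 0, sdlog = spec$phase_program_sd),
      nrow = n_genes, dimnames = list(gene_info$gene_id, c("dry", "early", "main"))
    )
    n_samples <- nrow(metadata)
    abund <- matrix(
      rlnorm(spec$n_mags * n_samples, meanlog = 0, sdlog = spec$abundance_log_sd),
      nrow = spec$n_mags, dimnames = list(mags, metadata$sample_id)
    )

    counts <- matrix(0, nrow = n_genes, ncol = n_samples,
                     dimnames = list(gene_info$gene_id, metadata$sample_id))
    mag_idx <- match(gene_info$mag_id, mags)
    for (j in seq_len(n_samples)) {
      ph <- as.character(metadata$phase[j])
      mu_rel <- base * phase_mult[, ph] * abund[mag_idx, j]
      tot <- sum(mu_rel)
      mu <- if (tot > 0) mu_rel / tot * spec$depth else mu_rel * 0
      counts[, j] <- rnbinom(n_genes, mu = mu, size = 1 / spec$dispersion)
    }

    list(
      counts = dplyr::bind_cols(
        tibble::tibble(gene_id = gene_info$gene_id),
        tibble::as_tibble(counts)
      ),
      gene_info = gene_info,
      metadata = metadata,
      truth = list(
        gene_base = setNames(base, gene_info$gene_id),
        phase_multipliers = phase_mult,
        mag_abundance = abund
      )
    )
  })
}

#' Generate a synthetic headspace H2 series
#'
#' Forward model [predict_h2()] plus iid Gaussian measurement noise, floored
#' at zero.
#'
#' @param k First-order uptake rate constant, per hour.
#' @param c0 Initial mixing ratio, ppmv (default 4, a typical H2 spike).
#' @param c_atm Atmospheric asymptote, ppmv (default 0.53).
#' @param times_h Sampling times in hours.
#' @param noise_sd Gaussian noise SD in ppmv.
#' @param seed Integer seed.
#' @return A tibble `time_h`, `h2_ppmv`.
#' @examples
#' gen_h2_series(k = 0.38, seed = 1)
#' @export
gen_h2_series <- function(k,
                          c0 = 4,
                          c_atm = 0.53,
                          times_h = seq(0, 12, length.out = 10),
                          noise_sd = 0.05,
                          seed = 1) {
  stopifnot(k >= 0, noise_sd >= 0)
  withr::with_seed(as.integer(seed), {
    y <- predict_h2(times_h, k, c0, c_atm) + rnorm(length(times_h), 0, noise_sd)
    tibble::tibble(time_h = times_h, h2_ppmv = pmax(y, 0))
  })
}
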