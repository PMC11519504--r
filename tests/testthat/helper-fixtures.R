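# Monte-Carlo oracle for the Poisson uncertainty of the 2H atom fraction:
# draw independent Poisson counts at the given means and take the empirical
# SD of the resulting at% values.
mc_atpercent_sd <- function(h1_mean, h2_mean, n_draws = 1e5, seed = 42) {
  withr::with_seed(seed, {
    h1 <- stats::rpois(n_draws, h1_mean)
    h2 <- stats::rpois(n_draws, h2_mean)
    stats::sd(100 * h2 / (h1 + h2))
  })
}

# Tiny deterministic ROI table used across tests.
roi_fixture <- function() {
  tibble::tibble(
    sample_id = "t24h",
    timepoint_h = 24,
    roi_id = c("a", "b", "c"),
    h1_counts = c(99400, 99950, 9900),
    h2_counts = c(600, 50, 100)
  )
}

ctrl_summary_fixture <- function(mean = 0.022, sd = 0.002, n = 30) {
  tibble::tibble(mean_at_percent = mean, sd_at_percent = sd, n_cells = n)
}
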