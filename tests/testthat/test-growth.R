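het <- physiology_scenario("heterotroph")
chemo <- physiology_scenario("chemoautotroph")

test_that("the enrichment-to-growth model reproduces the worked example", {
  cells <- tibble::tibble(
    timepoint_h = 24, f_at_percent = 0.60, sigma_at_percent = 0.01
  )
  out <- biomass_generation_rate(cells) # natural-abundance baseline

  mu_het <- out$mu_bar_per_h[out$scenario == "heterotroph"]
  mu_chemo <- out$mu_bar_per_h[out$scenario == "chemoautotroph"]

  # frozen from direct evaluation of the model with the scenario constants
  expect_equal(mu_het, 0.005222093, tolerance = 1e-6)
  expect_equal(mu_chemo, 0.001560743, tolerance = 1e-6)
  expect_equal(out$tau_days[out$scenario == "heterotroph"], 5.530567,
               tolerance = 1e-6)
  expect_equal(out$tau_days[out$scenario == "chemoautotroph"], 18.504736,
               tolerance = 1e-6)
})

test_that("cells at or below the baseline get a zero rate, flagged", {
  cells <- tibble::tibble(
    timepoint_h = 24, f_at_percent = 0.0156, sigma_at_percent = 0.001
  )
  out <- biomass_generation_rate(cells)
  expect_true(all(out$mu_bar_per_h == 0))
  expect_true(all(out$below_baseline))
  expect_true(all(is.infinite(out$tau_days)))
})

test_that("saturated enrichment is flagged as NA, never clipped", {
  # heterotroph labeling asymptote: baseline + (a_w F_D2O - F_H2O)/k ~ 4.98 at%
  cells <- tibble::tibble(
    timepoint_h = 24, f_at_percent = 6, sigma_at_percent = 0.01
  )
  out <- biomass_generation_rate(cells, scenarios = het)
  expect_true(out$saturated)
  expect_true(is.na(out$mu_bar_per_h))
  expect_true(is.na(out$tau_days))

  # the same cell is unsaturated under the chemoautotroph constants
  out2 <- biomass_generation_rate(cells, scenarios = chemo)
  expect_false(out2$saturated)
  expect_true(out2$mu_bar_per_h > 0)
})

test_that("forward and inverse enrichment maps are mutual inverses", {
  cfg <- incubation_config()
  mu_grid <- c(0, 1e-6, 1e-4, 0.001, 0.00522, 0.05, 0.3, 1)
  # t = 1 h keeps the exponential well away from the labeling asymptote
  # across the whole grid; at t = 24 h the upper rates saturate the label
  # to within double precision of the asymptote, so a reduced grid is used.
  for (scen in list(het, chemo)) {
    for (setup in list(list(t = 1, mu = mu_grid),
                       list(t = 24, mu = mu_grid[mu_grid <= 0.05]))) {
      f <- invert_enrichment(setup$mu, scen, cfg, t_incub_h = setup$t)
      cells <- tibble::tibble(
        timepoint_h = setup$t, f_at_percent = f, sigma_at_percent = 0
      )
      mu_back <- biomass_generation_rate(cells, scenarios = scen)$mu_bar_per_h
      expect_equal(mu_back, setup$mu, tolerance = 1e-10)
    }
  }

  # endpoint identities of the forward map
  expect_equal(invert_enrichment(0, het, cfg, 24), 0.0156)
  asymptote <- 0.0156 + (het$a_w * 30 - 0.0156) / het$k_corr
  expect_equal(invert_enrichment(1e6, het, cfg, 24), asymptote)
  expect_equal(
    round(invert_enrichment(0.00522, het, cfg, 24), 2), 0.60
  )
})

test_that("rates increase and replication times decrease with enrichment", {
  f_grid <- seq(0.02, 4.5, length.out = 60)
  cells <- tibble::tibble(
    timepoint_h = 24, f_at_percent = f_grid, sigma_at_percent = 0
  )
  for (scen in list(het, chemo)) {
    out <- biomass_generation_rate(cells, scenarios = scen)
    ok <- !out$saturated
    expect_true(all(diff(out$mu_bar_per_h[ok]) > 0))
    expect_true(all(diff(out$tau_days[ok]) < 0))
  }
})

test_that("heterotroph replication times undercut chemoautotroph ones", {
  f_grid <- seq(0.02, 2, length.out = 40)
  cells <- tibble::tibble(
    timepoint_h = 24, f_at_percent = f_grid, sigma_at_percent = 0
  )
  out <- biomass_generation_rate(cells)
  wide <- tidyr::pivot_wider(
    out[, c("f_at_percent", "scenario", "tau_days")],
    names_from = "scenario", values_from = "tau_days"
  )
  expect_true(all(wide$heterotroph < wide$chemoautotroph))
})

test_that("replication time converts rates under both readings", {
  expect_equal(replication_time(log(2) / 24, mode = "growth"), 1)
  expect_equal(replication_time(0.1 / 24, mode = "regeneration"), 10)
  expect_equal(round(replication_time(0.00522), 2), 5.53)
  expect_identical(replication_time(0), Inf)
  expect_identical(replication_time(-0.1), Inf)
  expect_identical(replication_time(NA_real_), NA_real_)
})

test_that("the cohort median commutes with the monotone growth transform", {
  withr::with_seed(7, {
    f <- sort(stats::runif(31, 0.05, 2)) # odd-sized cohort
  })
  cells <- tibble::tibble(
    timepoint_h = 24, f_at_percent = f, sigma_at_percent = 0
  )
  out <- biomass_generation_rate(cells, scenarios = het)
  tau_of_median_f <- biomass_generation_rate(
    tibble::tibble(timepoint_h = 24, f_at_percent = median(f),
                   sigma_at_percent = 0),
    scenarios = het
  )$tau_days
  expect_equal(median(out$tau_days), tau_of_median_f)
})

test_that("the control baseline is resolved override > measured > natural", {
  cells <- tibble::tibble(
    timepoint_h = 24, f_at_percent = 0.60, sigma_at_percent = 0.01
  )
  ctrl <- ctrl_summary_fixture(mean = 0.030)

  with_ctrl <- biomass_generation_rate(cells, control = ctrl, scenarios = het)
  expect_equal(with_ctrl$baseline_at_percent, 0.030)

  override <- biomass_generation_rate(
    cells, control = ctrl, scenarios = het,
    config = incubation_config(f_ctrl_override = 0.050)
  )
  expect_equal(override$baseline_at_percent, 0.050)

  bare <- biomass_generation_rate(cells, scenarios = het)
  expect_equal(bare$baseline_at_percent, 0.0156)

  # a higher baseline always means a lower inferred rate
  expect_lt(with_ctrl$mu_bar_per_h, bare$mu_bar_per_h)
  expect_lt(override$mu_bar_per_h, with_ctrl$mu_bar_per_h)
})
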