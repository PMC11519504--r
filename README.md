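# biocrustr

Desert biological soil crusts (biocrusts) spend most of their existence dry
and metabolically silent; their microbial communities wake up, work, and
shut down again inside rain pulses that often last a single day. `biocrustr`
implements the quantitative backbone of a rewetting experiment on such
crusts, for microbial ecologists who run (or re-analyze) heavy-water
labeling, genome-resolved metatranscriptomics and trace-gas assays on the
same samples:

1. **Single-cell activity and growth from heavy-water SIP + NanoSIMS.**
   Per-cell ion counts are converted to ²H atom fractions
   `F = ²H⁻/(¹H⁻+²H⁻)` with the Poisson counting uncertainty

   σ = 100/(¹H⁻+²H⁻)² · √((¹H⁻)²·²H⁻ + ¹H⁻·(²H⁻)²)  [at%]

   Cells are called anabolically active only if `F` exceeds the
   dead-control mean + 3 SD **and** the enrichment over the control mean
   exceeds 3σ (joint confidence 99.86%). For active cells the biomass
   generation rate is inverted from the labeling model

   μ̄ = −ln(1 − k·(F − F_ctrl)/(a_w·F_D₂O − F_H₂O)) / t

   under bracketing physiology scenarios — heterotrophy (k = 1.69,
   a_w = 0.28) and chemoautotrophy (k = 1.49, a_w = 0.79) — and converted to
   a replication time τ = ln2/μ̄ (growth) or 1/μ̄ (regeneration).
   Dead-time and QSA count corrections are included.

2. **Genome-resolved transcriptome normalization and ordination.** Gene
   counts are length-normalized and scaled to TPM either per sample (bulk)
   or per MAG, so every population's transcripts sum to one million in each
   sample — which removes the strong replicate-to-replicate swings in MAG
   abundance that otherwise mask hydration-phase expression programs.
   Quantitative Jaccard distances (2B/(1+B) with B the Bray–Curtis
   dissimilarity), ANOSIM with permutation p-values, UPGMA dendrograms and
   Newick/TSV exports provide the ordination statistics.

3. **Gas-flux analytics.** Respired CO₂ is partitioned into organic and
   inorganic sources by two end-member δ¹³C mixing,
   `fSIC = (δ¹³C_CO₂ − δ¹³C_SOC)/(δ¹³C_SIC − δ¹³C_SOC)`, and headspace H₂
   drawdown toward the atmospheric level (0.53 ppmv) is fitted with
   first-order kinetics `C(t) = C_atm + (C₀ − C_atm)·e^(−kt)`.

4. **Seeded synthetic data generators** for all three stages (latent
   active/inactive cells with lognormal replication times mapped through
   the forward labeling model to binomial ion counts; MAG-structured
   negative-binomial count matrices with phase-dependent programs and
   fluctuating MAG abundances; noisy exponential H₂ series), so the full
   pipeline runs and is testable at desk scale.

## Worked example

Simulate a labeling experiment (240 cells per time point at 3/6/12/24 h,
95% active, replication times lognormal around 5.6 d), classify cells
against a simulated dead control and summarize each cohort:

```r
library(biocrustr)
library(dplyr)

spec <- cell_cohort_spec()
sim  <- gen_cell_cohort(spec, seed = 1)
ctrl <- gen_dead_control(spec, seed = 2)

cohort_summary(sim$roi, ctrl) |>
  filter(scenario == "heterotroph") |>
  select(timepoint_h, n_active, frac_active, median_tau_days,
         frac_divide_within_1d)
#>   timepoint_h n_active frac_active median_tau_days frac_divide_within_1d
#> 1           3      223       0.929            4.27                0.0708
#> 2           6      221       0.921            6.24                0.0625
#> 3          12      229       0.954            4.80                0.0750
#> 4          24      227       0.946            5.67                0.0375
```

The recovered active fractions sit at the generator's 95% (within binomial
noise), the median replication time of active cells tracks the latent
5.6-day median, and only ~4–8% of all measured cells could double within a
one-day rain event.

The published 24-h median single-cell ²H content of 0.60 at% converts to
replication times directly:

```r
tibble::tibble(timepoint_h = 24, f_at_percent = 0.60,
               sigma_at_percent = 0.01) |>
  biomass_generation_rate() |>
  select(scenario, mu_bar_per_h, tau_days)
#>   scenario       mu_bar_per_h tau_days
#> 1 heterotroph         0.00522     5.53
#> 2 chemoautotroph      0.00156    18.5
```

i.e. a median doubling time of ~5.5 days if the cells are heterotrophs and
~18.5 days if they are chemoautotrophs.

Fit an H₂ uptake rate constant to a noisy synthetic wet-crust series:

```r
s <- gen_h2_series(k = 0.38, seed = 3)
fit_h2_rate_constant(s)
#> First-order H2 uptake fit (nls), C_atm fixed at 0.53 ppmv
#>   k = 0.3778 per h, C0 = 3.955 ppmv, residual sigma = 0.0424 ppmv (n = 10)
```

## See also

The methods vignette (`vignettes/biocrust-rewetting.Rmd`) documents the
models, their assumptions, all tunable constants, what the synthetic
generators do and do not emulate, and the package's numerical choices.
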