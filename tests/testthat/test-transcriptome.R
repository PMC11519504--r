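two_gene_info <- tibble::tibble(
  gene_id = c("g1", "g2"), mag_id = "m1", length_bp = c(1000, 2000)
)

test_that("length normalization divides by gene length in kilobases", {
  counts <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(100, 100),
                           s2 = c(0, 50))
  tc <- length_normalize(counts, two_gene_info)
  expect_equal(tc$s1, c(100, 50))
  expect_equal(tc$s2, c(0, 25))

  expect_error(
    length_normalize(
      tibble::tibble(gene_id = "gX", s1 = 1), two_gene_info
    ),
    "gX"
  )
})

test_that("per-MAG TPM weights by length then rescales to one million", {
  equal_len <- tibble::tibble(gene_id = c("g1", "g2"), mag_id = "m1",
                              length_bp = 1000)
  counts <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(1, 3))
  expect_equal(
    tpm_normalize(counts, equal_len, "per_mag")$s1, c(250000, 750000)
  )

  counts2 <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(100, 100))
  tpm2 <- tpm_normalize(counts2, two_gene_info, "per_mag")
  expect_equal(tpm2$s1, c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
})

test_that("bulk columns and per-MAG blocks sum to one million", {
  sim <- gen_mag_counts(
    mag_experiment_spec(n_mags = 4, genes_per_mag = c(10, 20)), seed = 9
  )
  samples <- setdiff(names(sim$counts), "gene_id")

  bulk <- tpm_normalize(sim$counts, sim$gene_info, "bulk")
  for (s in samples) {
    expect_equal(sum(bulk[[s]]), 1e6, tolerance = 1e-6)
  }

  pm <- tpm_normalize(sim$counts, sim$gene_info, "per_mag")
  mag <- sim$gene_info$mag_id[match(pm$gene_id, sim$gene_info$gene_id)]
  for (s in samples) {
    sums <- tapply(pm[[s]], mag, sum)
    nonzero <- tapply(sim$counts[[s]], mag, sum) > 0
    expect_equal(as.numeric(sums[nonzero]), rep(1e6, sum(nonzero)),
                 tolerance = 1e-6)
  }
})

test_that("per-MAG TPM is invariant to MAG-abundance rescaling; bulk is not", {
  sim <- gen_mag_counts(
    mag_experiment_spec(n_mags = 3, genes_per_mag = c(8, 12)), seed = 4
  )
  counts <- sim$counts
  target_mag <- sim$gene_info$mag_id[1]
  in_mag <- sim$gene_info$gene_id[sim$gene_info$mag_id == target_mag]
  scaled <- counts
  s1 <- setdiff(names(counts), "gene_id")[1]
  scaled[[s1]][scaled$gene_id %in% in_mag] <-
    scaled[[s1]][scaled$gene_id %in% in_mag] * 10

  pm0 <- tpm_normalize(counts, sim$gene_info, "per_mag")
  pm1 <- tpm_normalize(scaled, sim$gene_info, "per_mag")
  expect_equal(pm1[[s1]], pm0[[s1]], tolerance = 1e-9)

  b0 <- tpm_normalize(counts, sim$gene_info, "bulk")
  b1 <- tpm_normalize(scaled, sim$gene_info, "bulk")
  expect_gt(max(abs(b1[[s1]] - b0[[s1]])), 1)
})

test_that("zero-signal MAG blocks stay zero rather than NaN", {
  gi <- tibble::tibble(gene_id = c("g1", "g2"), mag_id = c("m1", "m2"),
                       length_bp = 1000)
  counts <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(10, 0))
  pm <- tpm_normalize(counts, gi, "per_mag")
  expect_equal(pm$s1, c(1e6, 0))
  expect_false(anyNA(pm$s1))
})

test_that("MAG transcript shares sum to one and match known splits", {
  gi <- tibble::tibble(gene_id = c("g1", "g2"), mag_id = c("m1", "m2"),
                       length_bp = 1000)
  one <- mag_transcript_share(
    tibble::tibble(gene_id = c("g1", "g2"), s1 = c(7, 0)), gi
  )
  expect_equal(one$share[one$mag_id == "m1"], 1)

  even <- mag_transcript_share(
    tibble::tibble(gene_id = c("g1", "g2"), s1 = c(5, 5)), gi
  )
  expect_equal(even$share, c(0.5, 0.5))
})

test_that("generator abundance multipliers are recovered from shares", {
  spec <- mag_experiment_spec(
    n_mags = 5, genes_per_mag = c(30, 40), dispersion = 0.05
  )
  sim <- gen_mag_counts(spec, seed = 21)
  shares <- mag_transcript_share(sim$counts, sim$gene_info)

  # expected share from the truth: abundance x program mass, normalized.
  tc_mass <- function(sample) {
    ph <- as.character(sim$metadata$phase[sim$metadata$sample_id == sample])
    per_gene <- sim$truth$gene_base *
      sim$truth$phase_multipliers[, ph] /
      (sim$gene_info$length_bp / 1000) *
      sim$truth$mag_abundance[sim$gene_info$mag_id, sample]
    m <- tapply(per_gene, sim$gene_info$mag_id, sum)
    setNames(as.numeric(m / sum(m)), names(m))
  }
  for (s in sim$metadata$sample_id[1:4]) {
    expected <- tc_mass(s)
    observed <- shares$share[shares$sample_id == s]
    names(observed) <- shares$mag_id[shares$sample_id == s]
    expect_equal(observed[names(expected)], expected, tolerance = 0.12)
  }
})

test_that("hydration phases map sampled time points and reject others", {
  expect_equal(
    as.character(assign_phase(c(0, 0.25, 0.5, 3, 6, 12, 39, 55))),
    c("dry", "early", "early", "main", "main", "main", "dry", "dry")
  )
  expect_error(assign_phase(1.5), "unknown time point")
})

test_that("quantitative Jaccard matches hand values and is a metric on [0,1]", {
  m <- rbind(a = c(2, 2), b = c(1, 1), c = c(1, 0), d = c(0, 1))
  d <- as.matrix(jaccard_dist(m))
  expect_equal(d["a", "b"], 0.5) # B = 1/3, D = 2B/(1+B)
  expect_equal(d["c", "d"], 1)   # disjoint supports
  expect_equal(diag(d), c(a = 0, b = 0, c = 0, d = 0))
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))

  # binary mode ignores abundances
  db <- as.matrix(jaccard_dist(m, binary = TRUE))
  expect_equal(db["a", "b"], 0)

  expect_error(jaccard_dist(rbind(a = c(0, 0), b = c(1, 1))), "all-zero")
})

test_that("ANOSIM hits R = 1 for perfect separation and validates groups", {
  pts <- rbind(matrix(stats::rnorm(10, 0, 0.01), 5),
               matrix(stats::rnorm(10, 5, 0.01), 5))
  fit <- anosim_test(stats::dist(pts), rep(c("a", "b"), each = 5),
                     n_perm = 199, seed = 1)
  expect_equal(fit$statistic, 1)
  expect_lt(fit$p_value, 0.05)
  expect_true(abs(fit$statistic) <= 1)
  expect_s3_class(tidy(fit), "tbl_df")

  expect_error(
    anosim_test(stats::dist(pts), c(rep("a", 9), "b"), n_perm = 99),
    ">= 2 groups"
  )
})

test_that("ANOSIM p-values are seed-reproducible and never exactly zero", {
  pts <- matrix(stats::rnorm(24), 8)
  d <- stats::dist(pts)
  g <- rep(c("a", "b"), each = 4)
  f1 <- anosim_test(d, g, n_perm = 199, seed = 9)
  f2 <- anosim_test(d, g, n_perm = 199, seed = 9)
  expect_equal(f1$p_value, f2$p_value)
  expect_gte(f1$p_value, 1 / 200)
})

test_that("UPGMA merges follow average linkage with monotone heights", {
  d3 <- matrix(c(0, 0.1, 0.5, 0.1, 0, 0.5, 0.5, 0.5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- upgma_cluster(stats::as.dist(d3))
  expect_equal(hc$height, c(0.1, 0.5))

  d2 <- stats::as.dist(matrix(c(0, 0.4, 0.4, 0), 2,
                              dimnames = list(c("x", "y"), c("x", "y"))))
  expect_equal(upgma_cluster(d2)$height, 0.4)

  same <- stats::dist(rbind(a = c(1, 1), b = c(1, 1), c = c(1, 1)))
  expect_equal(upgma_cluster(same)$height, c(0, 0))

  sim <- gen_mag_counts(
    mag_experiment_spec(n_mags = 4, genes_per_mag = c(10, 15)), seed = 2
  )
  dd <- jaccard_dist(sample_profiles(
    tpm_normalize(sim$counts, sim$gene_info, "per_mag")
  ))
  hh <- upgma_cluster(dd)
  expect_true(all(diff(hh$height) >= -1e-12))

  expect_error(upgma_cluster(stats::dist(rbind(a = 1))), "at least 2")

  nwk <- dendrogram_newick(hc)
  expect_match(nwk, "^\\(")
  expect_s3_class(ape::read.tree(text = nwk), "phylo")
})
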