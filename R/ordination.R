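#' Quantitative Jaccard distances between sample profiles
#'
#' Computes pairwise dissimilarities between sample abundance profiles using
#' the quantitative Jaccard (Ruzicka) form: with the Bray-Curtis
#' dissimilarity `B = sum|x_i - y_i| / sum(x_i + y_i)`, the distance is
#' `D = 2B / (1 + B)`, bounded in \[0, 1\]. With `binary = TRUE` profiles are
#' reduced to presence/absence (classical Jaccard). Jaccard-type distances
#' give no weight to joint absences, which suits sparse relative-abundance
#' data where a missing transcript may simply reflect sequencing depth.
#'
#' @param profiles Samples-by-features abundance table: either a numeric
#'   matrix with sample rownames or a tibble with a `sample_id` column and
#'   numeric feature columns (e.g. a transposed TPM table).
#' @param binary Use presence/absence instead of abundances (default FALSE).
#' @return A [stats::dist] object labeled with sample ids.
#' @examples
#' m <- rbind(a = c(2, 2), b = c(1, 1))
#' jaccard_dist(m) # 0.5
#' @export
jaccard_dist <- function(profiles, binary = FALSE) {
  m <- as_profile_matrix(profiles)
  zero_rows <- rowSums(m) == 0
  if (any(zero_rows)) {
    abort(paste0(
      "all-zero profile(s): ", paste(rownames(m)[zero_rows], collapse = ", "),
      "; drop signal-free samples before computing distances"
    ))
  }
  vegan::vegdist(m, method = "jaccard", binary = binary)
}

as_profile_matrix <- function(profiles) {
  if (is.data.frame(profiles) && "sample_id" %in% names(profiles)) {
    m <- as.matrix(profiles[setdiff(names(profiles), "sample_id")])
    rownames(m) <- profiles$sample_id
  } else {
    m <- as.matrix(profiles)
  }
  if (!is.numeric(m)) abort("profiles must be numeric")
  if (any(m < 0, na.rm = TRUE)) abort("abundances must be non-negative")
  m
}

#' Transpose a TPM/count tibble into sample profiles
#'
#' Helper to turn a `gene_id` + sample-column table into the
#' samples-by-features layout used by [jaccard_dist()].
#'
#' @param tpm Tibble with `gene_id` and one numeric column per sample.
#' @return Numeric matrix, samples in rows, genes in columns.
#' @export
sample_profiles <- function(tpm) {
  check_count_table(tpm)
  m <- t(as.matrix(tpm[setdiff(names(tpm), "gene_id")]))
  colnames(m) <- tpm$gene_id
  m
}

#' Analysis of similarities (ANOSIM)
#'
#' One-sided rank-based permutation test for separation of a priori sample
#' groups on a distance matrix. The statistic
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`
#' lies in \[-1, 1\]; the p-value is `(1 + #permuted R >= observed) /
#' (n_perm + 1)`, so it can never be exactly zero. Computation delegates to
#' [vegan::anosim()] under a locally fixed seed.
#'
#' @param dist A distance matrix ([stats::dist] or square symmetric matrix).
#' @param groups Group labels, one per sample; at least two groups with at
#'   least two members each.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional integer seed for reproducible permutations; the
#'   global RNG state is left untouched.
#' @return An object of class `anosim_fit` with elements `statistic`
#'   (R), `p_value`, `n_perm`, `n_samples`, `groups` and the underlying
#'   vegan fit. [tidy()] and [glance()] methods return one-row tibbles.
#' @examples
#' m <- rbind(matrix(rnorm(20), 4), matrix(rnorm(20, 3), 4))
#' rownames(m) <- paste0("s", 1:8)
#' fit <- anosim_test(dist(m), rep(c("a", "b"), each = 4),
#'                    n_perm = 199, seed = 1)
#' tidy(fit)
#' @export
anosim_test <- function(dist, groups, n_perm = 9999, seed = NULL) {
  d <- stats::as.dist(dist)
  n <- attr(d, "Size")
  groups <- as.factor(groups)
  if (length(groups) != n) {
    abort("length(groups) must match the number of samples in dist")
  }
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L)) {
    abort("need >= 2 groups with >= 2 members each")
  }
  run <- function() vegan::anosim(d, grouping = groups, permutations = n_perm)
  fit <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(
    list(
      statistic = unname(fit$statistic),
      p_value = unname(fit$signif),
      n_perm = n_perm,
      n_samples = n,
      groups = tab,
      seed = seed,
      vegan_fit = fit
    ),
    class = "anosim_fit"
  )
}

#' @export
print.anosim_fit <- function(x, ...) {
  cat("ANOSIM:", x$n_samples, "samples,",
      length(x$groups), "groups,", x$n_perm, "permutations\n")
  cat(sprintf("  R = %.4f, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' @rdname anosim_test
#' @param x An `anosim_fit` object.
#' @param ... Unused.
#' @export
tidy.anosim_fit <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    p.value = x$p_value,
    n_perm = x$n_perm,
    n_samples = x$n_samples,
    n_groups = length(x$groups)
  )
}

#' @rdname anosim_test
#' @export
glance.anosim_fit <- function(x, ...) tidy.anosim_fit(x)

#' Average-linkage (UPGMA) hierarchical clustering of samples
#'
#' Agglomerative clustering of a distance matrix with average linkage, as
#' used for sample dendrograms alongside ordination. Merge heights are
#' non-decreasing by construction for UPGMA.
#'
#' @param dist Distance matrix ([stats::dist] or square symmetric matrix).
#' @return An [stats::hclust] object.
#' @examples
#' upgma_cluster(dist(rbind(a = 0, b = 0.1, c = 0.5)))
#' @export
upgma_cluster <- function(dist) {
  d <- stats::as.dist(dist)
  if (attr(d, "Size") < 2L) abort("need at least 2 samples to cluster")
  hclust(d, method = "average")
}

#' Export a sample dendrogram in Newick format
#'
#' @param hc An [stats::hclust] object (e.g. from [upgma_cluster()]).
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to `file`.
#' @export
dendrogram_newick <- function(hc, file = NULL) {
  stopifnot(inherits(hc, "hclust"))
  phy <- ape::as.phylo(hc)
  if (is.null(file)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = file)
    invisible(ape::write.tree(phy))
  }
}

#' Write a square distance matrix as TSV
#'
#' Emits the labeled square form of a distance object, ready for external
#' ordination tools (NMDS is deliberately not reimplemented here).
#'
#' @param dist A [stats::dist] object.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_distance_matrix <- function(dist, file) {
  m <- as.matrix(dist)
  df <- tibble::as_tibble(m, rownames = "sample_id")
  readr::write_tsv(df, file)
  invisible(file)
}
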