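#' Convert read counts to length-normalized transcript counts
#'
#' Divides each gene's read count by its length in kilobases, turning read
#' counts into transcript counts (reads per kilobase). This is the first
#' step of both TPM normalizations.
#'
#' @param counts Tibble with a `gene_id` column and one numeric column per
#'   sample (featureCounts layout; see [read_feature_counts()]).
#' @param gene_info Tibble with `gene_id`, `mag_id`, `length_bp`.
#' @return Tibble of the same shape with counts replaced by transcript
#'   counts.
#' @examples
#' counts <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(100, 100))
#' genes <- tibble::tibble(gene_id = c("g1", "g2"), mag_id = "m1",
#'                         length_bp = c(1000, 2000))
#' length_normalize(counts, genes)
#' @export
length_normalize <- function(counts, gene_info) {
  check_count_table(counts)
  check_gene_info(gene_info)
  missing <- setdiff(counts$gene_id, gene_info$gene_id)
  if (length(missing) > 0) {
    abort(paste0(
      "no gene length for ", length(missing), " gene(s): ",
      paste(utils::head(missing, 5), collapse = ", "),
      if (length(missing) > 5) ", ..."
    ))
  }
  len_kb <- gene_info$length_bp[match(counts$gene_id, gene_info$gene_id)] / 1000
  dplyr::mutate(
    tibble::as_tibble(counts),
    dplyr::across(dplyr::where(is.numeric), ~ .x / len_kb)
  )
}

#' Bulk and per-MAG TPM normalization
#'
#' Translates length-normalized transcript counts into transcripts per
#' million (TPM) in one of two ways. `mode = "bulk"` rescales every sample
#' column so all transcripts in the sample sum to one million — the
#' conventional TPM. `mode = "per_mag"` rescales each (MAG, sample) block so
#' the transcripts attributed to each metagenome-assembled genome (MAG) sum
#' to one million within every sample.
#'
#' Per-MAG normalization removes the per-sample abundance of each population
#' from its expression profile: multiplying all counts of a MAG in a sample
#' by any constant leaves its per-MAG TPM unchanged. In communities where
#' population abundances swing several-fold between replicates this is what
#' lets within-population expression programs surface; bulk TPM confounds
#' them with abundance.
#'
#' MAG-sample blocks with zero total transcripts stay all-zero (no NaN).
#'
#' @param counts Read-count tibble (`gene_id` + sample columns).
#' @param gene_info Tibble with `gene_id`, `mag_id`, `length_bp`.
#' @param mode `"bulk"` or `"per_mag"`.
#' @return TPM tibble (`gene_id` + sample columns) with attribute
#'   `normalization` set to the mode.
#' @examples
#' counts <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(1, 3))
#' genes <- tibble::tibble(gene_id = c("g1", "g2"), mag_id = "m1",
#'                         length_bp = 1000)
#' tpm_normalize(counts, genes, mode = "per_mag")
#' @export
tpm_normalize <- function(counts, gene_info, mode = c("bulk", "per_mag")) {
  mode <- match.arg(mode)
  tc <- length_normalize(counts, gene_info)
  sample_cols <- setdiff(names(tc), "gene_id")
  scale_block <- function(x) {
    tot <- sum(x)
    if (tot > 0) x / tot * 1e6 else x * 0
  }
  if (mode == "bulk") {
    out <- dplyr::mutate(tc, dplyr::across(dplyr::all_of(sample_cols), scale_block))
  } else {
    mag <- gene_info$mag_id[match(tc$gene_id, gene_info$gene_id)]
    out <- tc |>
      dplyr::mutate(.mag = mag) |>
      dplyr::group_by(.data$.mag) |>
      dplyr::mutate(dplyr::across(dplyr::all_of(sample_cols), scale_block)) |>
      dplyr::ungroup() |>
      dplyr::select(-".mag")
  }
  attr(out, "normalization") <- mode
  out
}

#' Per-sample transcript share of each MAG
#'
#' Fraction of a sample's mapped transcripts (length-normalized counts)
#' attributable to each metagenome-assembled genome. Shares sum to one
#' within every sample.
#'
#' @inheritParams tpm_normalize
#' @return Long tibble: `sample_id`, `mag_id`, `share`.
#' @examples
#' counts <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(5, 5))
#' genes <- tibble::tibble(gene_id = c("g1", "g2"),
#'                         mag_id = c("m1", "m2"), length_bp = 1000)
#' mag_transcript_share(counts, genes)
#' @export
mag_transcript_share <- function(counts, gene_info) {
  tc <- length_normalize(counts, gene_info)
  sample_cols <- setdiff(names(tc), "gene_id")
  tc |>
    dplyr::mutate(mag_id = gene_info$mag_id[match(.data$gene_id, gene_info$gene_id)]) |>
    tidyr::pivot_longer(dplyr::all_of(sample_cols),
      names_to = "sample_id", values_to = "tc"
    ) |>
    dplyr::group_by(.data$sample_id, .data$mag_id) |>
    dplyr::summarise(tc = sum(.data$tc), .groups = "drop_last") |>
    dplyr::mutate(share = .data$tc / sum(.data$tc)) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "mag_id", "share")
}

#' Assign hydration phases to sampling time points
#'
#' The rewetting time series has three phases defined by water content: the
#' dry phase (samples at 0, 39 and 55 h — before hydration and during the
#' desiccation tail), the early hydration phase (15 and 30 min after the
#' simulated rain) and the main hydration phase (3, 6 and 12 h). Unknown
#' time points raise an error rather than snapping to the nearest phase.
#'
#' @param timepoint_h Numeric sampling times in hours.
#' @return Factor with levels `dry`, `early`, `main`.
#' @examples
#' assign_phase(c(0, 0.25, 6, 39))
#' @export
assign_phase <- function(timepoint_h) {
  stopifnot(is.numeric(timepoint_h))
  phase_map <- c(
    "0" = "dry", "39" = "dry", "55" = "dry",
    "0.25" = "early", "0.5" = "early",
    "3" = "main", "6" = "main", "12" = "main"
  )
  key <- as.character(timepoint_h)
  unknown <- unique(timepoint_h[!key %in% names(phase_map)])
  if (length(unknown) > 0) {
    abort(paste0(
      "unknown time point(s): ", paste(unknown, collapse = ", "),
      "; sampled times are 0, 0.25, 0.5, 3, 6, 12, 39, 55 h"
    ))
  }
  factor(unname(phase_map[key]), levels = c("dry", "early", "main"))
}

check_count_table <- function(counts) {
  stopifnot(is.data.frame(counts))
  if (!"gene_id" %in% names(counts)) abort("counts must have a gene_id column")
  if (anyDuplicated(counts$gene_id)) abort("gene_id must be unique")
  num <- vapply(counts[setdiff(names(counts), "gene_id")], is.numeric, logical(1))
  if (!all(num)) abort("all sample columns must be numeric")
  vals <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  if (any(vals < 0, na.rm = TRUE)) abort("counts must be non-negative")
  invisible(counts)
}

check_gene_info <- function(gene_info) {
  stopifnot(is.data.frame(gene_info))
  need <- c("gene_id", "mag_id", "length_bp")
  if (!all(need %in% names(gene_info))) {
    abort("gene_info must have columns gene_id, mag_id, length_bp")
  }
  if (anyDuplicated(gene_info$gene_id)) abort("gene_info gene_id must be unique")
  if (any(gene_info$length_bp < 1)) abort("gene lengths must be >= 1 bp")
  invisible(gene_info)
}
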