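#' Read a per-ROI ion-count table
#'
#' Tab-separated, one row per ROI, with header. Required columns:
#' `sample_id`, `timepoint_h`, `roi_id`, `h1_counts`, `h2_counts`; any
#' additional `*_counts`, rate or metadata columns are carried through.
#'
#' @param file Path to the TSV.
#' @return A tibble.
#' @export
read_roi_table <- function(file) {
  x <- readr::read_tsv(file, show_col_types = FALSE)
  need <- c("sample_id", "timepoint_h", "roi_id", "h1_counts", "h2_counts")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste("ROI table is missing column(s):", paste(miss, collapse = ", ")))
  }
  x
}

#' Read a featureCounts-style gene count table
#'
#' Accepts the native featureCounts output (columns `Geneid`, `Chr`,
#' `Start`, `End`, `Strand`, `Length`, then one column per sample; comment
#' lines starting with `#` are skipped) or any TSV with a `gene_id`/`Geneid`
#' column plus numeric sample columns.
#'
#' @param file Path to the TSV.
#' @return A list: `counts` (tibble `gene_id` + sample columns) and
#'   `gene_lengths` (tibble `gene_id`, `length_bp`; `NULL` when the file has
#'   no `Length` column).
#' @export
read_feature_counts <- function(file) {
  x <- readr::read_tsv(file, comment = "#", show_col_types = FALSE)
  id_col <- intersect(c("Geneid", "gene_id"), names(x))[1]
  if (is.na(id_col)) abort("no Geneid/gene_id column found")
  names(x)[names(x) == id_col] <- "gene_id"
  gene_lengths <- NULL
  if ("Length" %in% names(x)) {
    gene_lengths <- tibble::tibble(gene_id = x$gene_id, length_bp = x$Length)
  }
  drop <- intersect(c("Chr", "Start", "End", "Strand", "Length"), names(x))
  counts <- x[setdiff(names(x), drop)]
  check_count_table(counts)
  list(counts = counts, gene_lengths = gene_lengths)
}

#' Read a gene-to-MAG map and assemble gene info
#'
#' @param file TSV with columns `gene_id`, `mag_id` (a `length_bp` column is
#'   used if present).
#' @param gene_lengths Optional tibble `gene_id`, `length_bp` (e.g. from
#'   [read_feature_counts()]) joined onto the map.
#' @return A gene-info tibble (`gene_id`, `mag_id`, `length_bp`).
#' @export
read_gene_map <- function(file, gene_lengths = NULL) {
  x <- readr::read_tsv(file, show_col_types = FALSE)
  if (!all(c("gene_id", "mag_id") %in% names(x))) {
    abort("gene map must have columns gene_id and mag_id")
  }
  if (!is.null(gene_lengths)) {
    x <- dplyr::left_join(x, gene_lengths, by = "gene_id")
  }
  if (!"length_bp" %in% names(x)) {
    abort("supply gene lengths via the map file or the gene_lengths argument")
  }
  check_gene_info(x[, c("gene_id", "mag_id", "length_bp")])
}

#' Read sample metadata for an expression time series
#'
#' @param file TSV with columns `sample_id`, `timepoint_h`, `replicate` and
#'   optionally `water_content`. A `phase` column is added via
#'   [assign_phase()].
#' @return A tibble.
#' @export
read_sample_metadata <- function(file) {
  x <- readr::read_tsv(file, show_col_types = FALSE)
  need <- c("sample_id", "timepoint_h", "replicate")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste("metadata is missing column(s):", paste(miss, collapse = ", ")))
  }
  dplyr::mutate(x, phase = assign_phase(.data$timepoint_h))
}

#' Read headspace gas time series
#'
#' @param file TSV with columns `time_h`, `h2_ppmv` and optionally
#'   `replicate`, `treatment`.
#' @return A tibble.
#' @export
read_headspace_series <- function(file) {
  x <- readr::read_tsv(file, show_col_types = FALSE)
  if (!all(c("time_h", "h2_ppmv") %in% names(x))) {
    abort("headspace series must have columns time_h and h2_ppmv")
  }
  x
}

#' Write the per-cell activity/growth table as TSV
#'
#' @param cells A classified/growth-annotated cell tibble.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_cell_table <- function(cells, file) {
  readr::write_tsv(cells, file)
  invisible(file)
}
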