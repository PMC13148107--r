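# Cell-level quality control for SMART-seq2 plate data. The pipeline
# order is fixed: (1) ERCC spike-in outliers, (2) low-quality cells
# (library size / mitochondrial content), (3) neuronal-marker-positive
# selection. Boundary behaviour follows the printed strict inequalities:
# a cell with exactly 100,000 counts and exactly 5% mitochondrial
# content is retained.

qc_report <- function(filter, removed, params, n_in) {
  list(filter = filter, removed = removed, n_removed = length(removed),
       n_in = n_in, n_out = n_in - length(removed), params = params)
}

#' Remove ERCC spike-in outlier cells
#'
#' Flags cells whose ERCC count fraction exceeds
#' `median + mad_k * MAD` across cells (MAD is the scaled
#' [stats::mad()]). With no ERCC genes present this is the identity.
#'
#' @param m a [count_matrix()]
#' @param mad_k MAD multiplier for the outlier threshold
#' @return list with `matrix` (filtered `count_matrix`) and `report`
#'   (removed cell ids and the threshold applied)
#' @export
filter_ercc_outliers <- function(m, mad_k = 3) {
  stopifnot(inherits(m, "count_matrix"))
  n_in <- nrow(m$counts)
  if (!any(m$genes$is_ercc)) {
    return(list(matrix = m,
                report = qc_report("ercc_outlier", character(0),
                                   list(mad_k = mad_k, threshold = NA_real_), n_in)))
  }
  total <- library_sizes(m)
  frac <- Matrix::rowSums(m$counts[, m$genes$is_ercc, drop = FALSE]) / pmax(total, 1)
  thr <- median(frac) + mad_k * mad(frac)
  removed <- m$cells$cell_id[frac > thr]
  keep <- setdiff(m$cells$cell_id, removed)
  if (length(keep) == 0) abort("ERCC outlier filter removed every cell")
  list(matrix = subset_cells(m, keep),
       report = qc_report("ercc_outlier", removed,
                          list(mad_k = mad_k, threshold = thr), n_in))
}

#' Remove low-quality cells
#'
#' Drops cells with library size strictly below `min_counts` or
#' mitochondrial count fraction strictly above `max_mito_frac`
#' (defaults: 100,000 counts and 5%).
#'
#' @param m a [count_matrix()]
#' @param min_counts minimum library size (total counts, all genes)
#' @param max_mito_frac maximum tolerated mitochondrial count fraction
#' @return list with `matrix` and `report` as in [filter_ercc_outliers()]
#' @export
filter_low_quality <- function(m, min_counts = 1e5, max_mito_frac = 0.05) {
  stopifnot(inherits(m, "count_matrix"))
  n_in <- nrow(m$counts)
  total <- library_sizes(m)
  mito <- Matrix::rowSums(m$counts[, m$genes$is_mito, drop = FALSE]) / pmax(total, 1)
  bad <- total < min_counts | mito > max_mito_frac
  removed <- m$cells$cell_id[bad]
  if (all(bad))
    abort(sprintf("low-quality filter removed all %d cells (%d below %g counts, %d above %.3g mito fraction)",
                  n_in, sum(total < min_counts), min_counts,
                  sum(mito > max_mito_frac), max_mito_frac))
  list(matrix = subset_cells(m, m$cells$cell_id[!bad]),
       report = qc_report("low_quality", removed,
                          list(min_counts = min_counts,
                               max_mito_frac = max_mito_frac), n_in))
}

#' Keep cells expressing established neuronal markers
#'
#' Retains cells whose summed counts over the marker genes reach
#' `min_count`. An empty marker list is the identity (with a warning),
#' since the marker panel is a required user input on real data.
#'
#' @param m a [count_matrix()]
#' @param marker_ids marker gene ids; defaults to genes flagged
#'   `is_marker`
#' @param min_count minimum summed marker counts per cell
#' @return list with `matrix` and `report`
#' @export
filter_marker_positive <- function(m, marker_ids = NULL, min_count = 1) {
  stopifnot(inherits(m, "count_matrix"))
  n_in <- nrow(m$counts)
  if (is.null(marker_ids)) marker_ids <- m$genes$gene_id[m$genes$is_marker]
  if (length(marker_ids) == 0) {
    warn("no marker genes given; marker filter is the identity")
    return(list(matrix = m, report = qc_report("marker_positive", character(0),
                                               list(marker_ids = character(0),
                                                    min_count = min_count), n_in)))
  }
  unknown <- setdiff(marker_ids, m$genes$gene_id)
  if (length(unknown) > 0)
    abort(sprintf("unknown marker gene(s): %s", paste(unknown, collapse = ", ")))
  ms <- Matrix::rowSums(m$counts[, m$genes$gene_id %in% marker_ids, drop = FALSE])
  keep <- ms >= min_count
  if (!any(keep)) abort("marker filter removed every cell")
  list(matrix = subset_cells(m, m$cells$cell_id[keep]),
       report = qc_report("marker_positive", m$cells$cell_id[!keep],
                          list(marker_ids = marker_ids, min_count = min_count), n_in))
}

#' CPM normalisation with log2 transform
#'
#' `value = log2(1e6 * count / library_size + 1)` per cell. ERCC
#' spike-ins are excluded from the library size and dropped from the
#' output (they are not cellular transcripts); mitochondrial genes stay
#' in. Both choices are configurable.
#'
#' @param m a [count_matrix()]; every cell must have at least one count
#' @param exclude_ercc exclude spike-ins from library size and output
#' @param include_mito keep mitochondrial genes in the library size
#' @return a `normalized_matrix`: sparse `values` in log2(CPM+1) units
#'   plus the gene/cell tables (zero counts stay exactly zero)
#' @export
normalize_cpm_log <- function(m, exclude_ercc = TRUE, include_mito = TRUE) {
  stopifnot(inherits(m, "count_matrix"))
  keep_g <- rep(TRUE, ncol(m$counts))
  if (exclude_ercc) keep_g <- keep_g & !m$genes$is_ercc
  counts <- m$counts[, keep_g, drop = FALSE]
  lib_genes <- keep_g
  if (!include_mito) lib_genes <- lib_genes & !m$genes$is_mito
  lib <- Matrix::rowSums(m$counts[, lib_genes, drop = FALSE])
  if (any(lib == 0))
    abort("cells with zero counts present; run the QC filters first")
  vals <- counts
  vals@x <- log2(1e6 * vals@x / lib[vals@i + 1L] + 1)  # @i holds 0-based row index per entry
  structure(list(values = vals, genes = m$genes[keep_g, ], cells = m$cells,
                 unit = "log2(CPM+1)"),
            class = "normalized_matrix")
}

#' @method print normalized_matrix
#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d cells x %d genes [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' Run the full QC pipeline in the prescribed order
#'
#' ERCC outliers, then low-quality cells, then marker-positive
#' selection; the order matters because each threshold is computed on
#' the cells surviving the previous step.
#'
#' @inheritParams filter_ercc_outliers
#' @inheritParams filter_low_quality
#' @inheritParams filter_marker_positive
#' @return list with `matrix` (filtered counts) and `reports` (one per
#'   filter, in application order)
#' @export
run_qc <- function(m, mad_k = 3, min_counts = 1e5, max_mito_frac = 0.05,
                   marker_ids = NULL, min_count = 1) {
  s1 <- filter_ercc_outliers(m, mad_k = mad_k)
  s2 <- filter_low_quality(s1$matrix, min_counts = min_counts,
                           max_mito_frac = max_mito_frac)
  s3 <- filter_marker_positive(s2$matrix, marker_ids = marker_ids,
                               min_count = min_count)
  list(matrix = s3$matrix, reports = list(s1$report, s2$report, s3$report))
}

#' Summarise QC reports as a tibble
#' @param reports list of per-filter reports from [run_qc()]
#' @return tibble with one row per filter
#' @export
qc_summary <- function(reports) {
  dplyr::bind_rows(lapply(reports, function(r)
    tibble(filter = r$filter, n_in = r$n_in, n_removed = r$n_removed,
           n_out = r$n_out)))
}

#' Write QC reports (thresholds and removed cell ids) as JSON
#' @param reports list of per-filter reports
#' @param path output JSON path
#' @export
write_qc_report <- function(reports, path) {
  jsonlite::write_json(reports, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
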