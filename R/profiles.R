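# Subtype-level expression profiles: the two aligned matrices the
# anti-correlation screen correlates. "Intensity" is the arithmetic mean
# of log2(CPM+1) over a subtype's cells ("mean log-transformed CPM", not
# the log of the mean CPM); "breadth" is the fraction of cells with a
# detected (count > 0) transcript.

#' Construct subtype profiles
#'
#' @param mean_matrix subtype x gene matrix of mean log2(CPM+1)
#' @param fraction_matrix subtype x gene matrix of detection fractions
#' @param n_cells named per-subtype cell counts
#' @return a `subtype_profiles` object
#' @export
subtype_profiles <- function(mean_matrix, fraction_matrix, n_cells) {
  if (!identical(dim(mean_matrix), dim(fraction_matrix)))
    abort("mean and fraction matrices must share shape")
  if (!identical(rownames(mean_matrix), rownames(fraction_matrix)) ||
      !identical(colnames(mean_matrix), colnames(fraction_matrix)))
    abort("mean and fraction matrices must share axis labels")
  if (any(fraction_matrix < 0) || any(fraction_matrix > 1))
    abort("fraction entries must lie in [0, 1]")
  if (any(n_cells < 1)) abort("every subtype needs at least one cell")
  structure(list(subtypes = rownames(mean_matrix),
                 genes = colnames(mean_matrix),
                 mean_matrix = as.matrix(mean_matrix),
                 fraction_matrix = as.matrix(fraction_matrix),
                 n_cells = n_cells),
            class = "subtype_profiles")
}

#' @method print subtype_profiles
#' @export
print.subtype_profiles <- function(x, ...) {
  cat(sprintf("<subtype_profiles> %d subtypes x %d genes (%d-%d cells/subtype)\n",
              length(x$subtypes), length(x$genes),
              min(x$n_cells), max(x$n_cells)))
  invisible(x)
}

#' Aggregate normalized cells into subtype profiles
#'
#' @param nm a `normalized_matrix` from [normalize_cpm_log()]
#' @param labels per-cell subtype labels; defaults to the `subtype`
#'   column carried by the matrix. Every cell must be labelled and every
#'   subtype must keep at least one cell.
#' @return a [subtype_profiles()] object (subtypes in sorted label order)
#' @export
aggregate_profiles <- function(nm, labels = NULL) {
  stopifnot(inherits(nm, "normalized_matrix"))
  labels <- labels %||% nm$cells$subtype
  if (length(labels) != nrow(nm$values))
    abort("one label per cell required")
  if (any(is.na(labels))) abort("unlabelled cells present")
  labels <- as.character(labels)
  subtypes <- sort(unique(labels))
  grp <- factor(labels, levels = subtypes)
  n_cells <- as.integer(table(grp))
  names(n_cells) <- subtypes

  ind <- Matrix::sparseMatrix(i = as.integer(grp), j = seq_along(labels),
                              x = 1, dims = c(length(subtypes), length(labels)))
  mean_m <- as.matrix(ind %*% nm$values) / n_cells
  detected <- nm$values
  detected@x <- rep(1, length(detected@x))
  frac_m <- as.matrix(ind %*% detected) / n_cells
  dimnames(mean_m) <- dimnames(frac_m) <- list(subtypes, nm$genes$gene_id)
  subtype_profiles(mean_m, frac_m, n_cells)
}

#' Match query clusters to reference types by cosine similarity
#'
#' Each query subtype is assigned the reference type whose mean
#' expression vector (over the shared gene set) has the highest cosine
#' similarity; ties break lexicographically on the reference label.
#' All-zero query vectors cannot be normalised and are flagged
#' unassignable.
#'
#' @param query,reference [subtype_profiles()] objects
#' @param shared_genes gene ids used for matching; defaults to the
#'   intersection of the two gene universes
#' @return tibble with columns `cluster`, `reference_type`, `similarity`
#'   and `unassignable`
#' @export
cosine_match <- function(query, reference, shared_genes = NULL) {
  stopifnot(inherits(query, "subtype_profiles"),
            inherits(reference, "subtype_profiles"))
  shared_genes <- shared_genes %||% intersect(query$genes, reference$genes)
  if (length(shared_genes) == 0) abort("no shared genes to match on")
  missing_q <- setdiff(shared_genes, query$genes)
  missing_r <- setdiff(shared_genes, reference$genes)
  if (length(missing_q) || length(missing_r))
    abort("shared_genes must be present in both profiles")

  Q <- query$mean_matrix[, shared_genes, drop = FALSE]
  R <- reference$mean_matrix[, shared_genes, drop = FALSE]
  qn <- sqrt(rowSums(Q^2)); rn <- sqrt(rowSums(R^2))
  if (any(rn == 0)) abort("reference contains an all-zero profile")
  ref_order <- order(reference$subtypes)  # lexicographic tie-break

  purrr::map_dfr(seq_along(query$subtypes), function(i) {
    if (qn[i] == 0) {
      return(tibble(cluster = query$subtypes[i],
                    reference_type = NA_character_,
                    similarity = NA_real_, unassignable = TRUE))
    }
    sims <- as.vector(R %*% Q[i, ]) / (rn * qn[i])
    best <- ref_order[which.max(sims[ref_order])]
    tibble(cluster = query$subtypes[i],
           reference_type = reference$subtypes[best],
           similarity = sims[best], unassignable = FALSE)
  })
}

#' Persist subtype profiles as TSVs plus JSON metadata
#'
#' Layout: `mean.tsv` and `fraction.tsv` (subtypes as rows, genes as
#' columns, first column `subtype`) and `meta.json` (cell counts, unit).
#'
#' @param p a [subtype_profiles()]
#' @param dir output directory
#' @return the directory, invisibly; `read_profiles` the object
#' @export
write_profiles <- function(p, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("mean", "fraction")) {
    mat <- p[[paste0(nm, "_matrix")]]
    df <- dplyr::bind_cols(tibble(subtype = rownames(mat)), as_tibble(mat))
    readr::write_tsv(df, file.path(dir, paste0(nm, ".tsv")))
  }
  jsonlite::write_json(list(n_cells = as.list(p$n_cells),
                            unit = "log2(CPM+1)"),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(dir) {
  rd <- function(nm) {
    df <- readr::read_tsv(file.path(dir, paste0(nm, ".tsv")),
                          show_col_types = FALSE)
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- df$subtype
    mat
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  subtype_profiles(rd("mean"), rd("fraction"), unlist(meta$n_cells))
}
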