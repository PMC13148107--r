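# The anti-correlation screen: gate cell-surface molecules (CSMs) by
# expression, correlate every candidate against the target gene in both
# the intensity (mean log2(CPM+1)) and breadth (expression fraction)
# matrices, average the two Pearson coefficients into the integrated
# score, and rank ascending -- scores closest to -1 are the strongest
# inverse-expression candidates.

#' Gate CSMs on expression level and breadth
#'
#' Retains candidates with mean expression > `min_mean` log2(CPM+1) AND
#' expression fraction > `min_frac` in at least one subtype. Under the
#' default joint rule both thresholds must be exceeded in the *same*
#' subtype; `joint = FALSE` lets them be satisfied in different
#' subtypes. Both comparisons are strict.
#'
#' @param p a [subtype_profiles()]
#' @param csm_ids candidate cell-surface-molecule gene ids
#' @param min_mean expression-intensity threshold (log2(CPM+1))
#' @param min_frac expression-fraction threshold
#' @param joint require both thresholds in the same subtype
#' @return character vector of passing gene ids (in `csm_ids` order)
#' @export
filter_csms <- function(p, csm_ids, min_mean = 3, min_frac = 0.5,
                        joint = TRUE) {
  stopifnot(inherits(p, "subtype_profiles"))
  if (length(csm_ids) == 0) abort("empty CSM candidate list")
  unknown <- setdiff(csm_ids, p$genes)
  if (length(unknown) > 0)
    abort(sprintf("CSM id(s) not in profiles: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  keep <- vapply(csm_ids, function(g) {
    hi_mean <- p$mean_matrix[, g] > min_mean
    hi_frac <- p$fraction_matrix[, g] > min_frac
    if (joint) any(hi_mean & hi_frac) else any(hi_mean) && any(hi_frac)
  }, logical(1))
  csm_ids[keep]
}

#' Pearson product-moment correlation with explicit degeneracy handling
#'
#' A thin wrapper around [stats::cor()] that requires length >= 3 and
#' returns `NA` (with a warning) when either vector has zero variance,
#' where the coefficient is undefined.
#'
#' @param x,y numeric vectors of equal length
#' @return correlation in \[-1, 1\], or `NA_real_` if undefined
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) abort("missing values not allowed")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("zero-variance input: Pearson r undefined")
    return(NA_real_)
  }
  cor(x, y)
}

#' Dual-matrix anti-correlation scores against a target gene
#'
#' For each candidate, `r_cpm` is the Pearson correlation between its
#' subtype mean-expression column and the target's, `r_frac` the same on
#' the expression-fraction matrix, and the integrated score their mean
#' `(r_cpm + r_frac) / 2`. Candidates whose column has zero variance in
#' either matrix carry `NA` (the coefficient is undefined) and are
#' excluded from later ranking.
#'
#' @param p a [subtype_profiles()] with >= 3 subtypes
#' @param target target gene id (e.g. the orphan receptor); must have
#'   nonzero variance in both matrices
#' @param candidates candidate gene ids; the target itself is dropped
#' @param passed optional subset of `candidates` that passed
#'   [filter_csms()]; recorded in the `passed_filter` column (defaults
#'   to all)
#' @return a `screen_result` tibble: gene_id, r_cpm, r_frac, score,
#'   passed_filter
#' @export
anticorr_scores <- function(p, target, candidates, passed = candidates) {
  stopifnot(inherits(p, "subtype_profiles"))
  if (!target %in% p$genes) abort(sprintf("target '%s' not in profiles", target))
  if (length(p$subtypes) < 3) abort("need at least 3 subtypes to correlate")
  unknown <- setdiff(candidates, p$genes)
  if (length(unknown) > 0)
    abort(sprintf("candidate(s) not in profiles: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  tm <- p$mean_matrix[, target]
  tf <- p$fraction_matrix[, target]
  if (sd(tm) == 0) abort("target has zero variance in the mean-expression matrix")
  if (sd(tf) == 0) abort("target has zero variance in the expression-fraction matrix")

  candidates <- setdiff(candidates, target)
  res <- purrr::map_dfr(candidates, function(g) {
    cm <- p$mean_matrix[, g]; cf <- p$fraction_matrix[, g]
    r_cpm <- if (sd(cm) == 0) NA_real_ else cor(tm, cm)
    r_frac <- if (sd(cf) == 0) NA_real_ else cor(tf, cf)
    tibble(gene_id = g, r_cpm = r_cpm, r_frac = r_frac,
           score = (r_cpm + r_frac) / 2)
  })
  res$passed_filter <- res$gene_id %in% passed
  new_screen_result(res, target = target)
}

new_screen_result <- function(df, target) {
  structure(df, class = c("screen_result", class(df)), target = target)
}

#' Rank screen candidates by integrated score
#'
#' Stable ascending sort (most anti-correlated first) over candidates
#' with a defined score that passed the CSM filter; ties break
#' lexicographically on gene id. Ranks 1..n are assigned over all scored
#' genes and the first `min(top_k, n)` rows are returned.
#'
#' @param results a `screen_result` from [anticorr_scores()]
#' @param top_k shortlist length (the screen's default follows the
#'   top-10 convention)
#' @return the shortlist as a `screen_result` tibble with a `rank`
#'   column
#' @export
rank_candidates <- function(results, top_k = 10) {
  scored <- as_tibble(results)
  if ("passed_filter" %in% names(scored))
    scored <- dplyr::filter(scored, .data$passed_filter)
  scored <- dplyr::filter(scored, !is.na(.data$score))
  dropped <- nrow(results) - nrow(scored)
  if (nrow(scored) == 0) abort("no candidates with a defined score")
  if (dropped > 0)
    message(sprintf("%d candidate(s) excluded (undefined score or failed filter)", dropped))
  scored <- dplyr::arrange(scored, .data$score, .data$gene_id)
  scored$rank <- seq_len(nrow(scored))
  new_screen_result(head(scored, top_k), target = attr(results, "target"))
}

#' Ingest structure-prediction confidence scores
#'
#' Averages per-model inter-chain predicted TM (ipTM) scores per
#' candidate and sorts descending by the mean, the convention used to
#' rank predicted receptor-ligand complexes. Accepts a tibble with
#' `gene_id` plus one column per model (any number of `model_*`
#' columns), or a long tibble with columns `gene_id`, `iptm`.
#'
#' @param table ipTM table (wide `model_*` columns or long `iptm`)
#' @return tibble with `gene_id`, `mean_iptm`, `n_models`, sorted
#'   descending by `mean_iptm`
#' @export
ingest_iptm <- function(table) {
  table <- as_tibble(table)
  if (!"gene_id" %in% names(table)) abort("ipTM table needs a gene_id column")
  if ("iptm" %in% names(table)) {
    long <- dplyr::select(table, "gene_id", "iptm")
  } else {
    model_cols <- grep("^model", names(table), value = TRUE)
    if (length(model_cols) == 0) abort("no model_* or iptm columns found")
    long <- tidyr::pivot_longer(table[, c("gene_id", model_cols)],
                                dplyr::all_of(model_cols),
                                names_to = "model", values_to = "iptm")
    long <- dplyr::filter(long, !is.na(.data$iptm))
  }
  if (any(long$iptm < 0 | long$iptm > 1))
    abort("ipTM scores must lie in [0, 1]")
  if (any(table(long$gene_id) < 1)) abort("each candidate needs >= 1 model score")
  out <- dplyr::summarise(dplyr::group_by(long, .data$gene_id),
                          mean_iptm = mean(.data$iptm),
                          n_models = dplyr::n(), .groups = "drop")
  dplyr::arrange(out, dplyr::desc(.data$mean_iptm), .data$gene_id)
}

#' Join a screen shortlist with structure scores
#' @param shortlist ranked `screen_result` from [rank_candidates()]
#' @param iptm output of [ingest_iptm()]
#' @return the shortlist with `mean_iptm`/`n_models` columns merged in
#' @export
merge_structure_scores <- function(shortlist, iptm) {
  dplyr::left_join(shortlist, iptm, by = "gene_id")
}

#' Run the complete anti-correlation screen
#'
#' [filter_csms()] on the candidate universe, [anticorr_scores()]
#' against the target (all CSMs scored, filter outcome recorded), then
#' [rank_candidates()]; optionally merges an ipTM table.
#'
#' @inheritParams filter_csms
#' @inheritParams anticorr_scores
#' @inheritParams rank_candidates
#' @param iptm optional ipTM table for [ingest_iptm()]
#' @return list with `scores` (all scored CSMs) and `shortlist` (ranked
#'   top `top_k`)
#' @export
run_screen <- function(p, target, csm_ids, min_mean = 3, min_frac = 0.5,
                       joint = TRUE, top_k = 10, iptm = NULL) {
  passed <- filter_csms(p, csm_ids, min_mean = min_mean,
                        min_frac = min_frac, joint = joint)
  scores <- anticorr_scores(p, target, setdiff(csm_ids, target),
                            passed = passed)
  shortlist <- rank_candidates(scores, top_k = top_k)
  if (!is.null(iptm)) shortlist <- merge_structure_scores(shortlist, ingest_iptm(iptm))
  list(scores = scores, shortlist = shortlist)
}
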