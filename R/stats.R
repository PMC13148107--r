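# Statistical procedures for penetrance and binding comparisons:
# two-sided Fisher exact tests on 2x2 tables (probability-method
# two-sided p, as implemented by stats::fisher.test), Benjamini-Hochberg
# FDR, Sidak correction, repeated-measures two-way ANOVA with
# within-subject error strata, and Pearson correlation of per-glomerulus
# mis-innervation frequencies.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p by the probability method: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table. Degenerate
#' margins give p = 1.
#'
#' @param table 2x2 matrix of non-negative integers
#' @return the two-sided p-value
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    abort("table entries must be non-negative integers")
  if (sum(table) == 0) abort("all-zero table")
  fisher.test(table)$p.value
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `p_adj(i) = min_{j >= i} (m * p(j) / j)` on
#' the sorted list, capped at 1, in input order. The family is exactly
#' the set of p-values passed in one call.
#'
#' @param pvals numeric vector of p-values in \[0, 1\]
#' @return adjusted p-values, same order
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    abort("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for `m` comparisons.
#'
#' @param p raw p-value(s) in \[0, 1\]
#' @param m number of comparisons in the family (>= 1)
#' @return adjusted p-value(s)
#' @export
sidak_adjust <- function(p, m) {
  if (any(p < 0 | p > 1)) abort("p must lie in [0, 1]")
  if (m < 1) abort("m must be >= 1")
  1 - (1 - p)^m
}

#' Significance stars in the display convention
#' @param p (adjusted) p-values
#' @return character: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#'   otherwise `ns`
#' @export
p_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "ns")
}

#' Repeated-measures two-way ANOVA with Sidak pairwise contrasts
#'
#' Within-subject sum-of-squares decomposition for two crossed factors
#' with subject blocking (`aov` with `Error(subject/(A*B))` strata),
#' requiring a balanced complete design: every subject contributes
#' exactly one response per A x B cell. Pairwise A contrasts (paired
#' across subjects) are computed within each B level and Sidak-adjusted
#' over the B levels.
#'
#' @param data long tibble/data.frame
#' @param response,subject,a,b column names (strings) for the response,
#'   the subject/slide id, factor A (e.g. untransfected vs transfected)
#'   and factor B (e.g. construct)
#' @return an `rm_anova` object: list with `effects` (term, df_num,
#'   df_den, ss, F, p), `contrasts` (per B level: estimate, t, p,
#'   p_sidak, stars) and the model call details
#' @export
rm_two_way_anova <- function(data, response = "intensity",
                             subject = "experiment", a = "group",
                             b = "construct") {
  df <- tibble(y = data[[response]],
               subj = factor(data[[subject]]),
               A = factor(data[[a]]),
               B = factor(data[[b]]))
  if (anyNA(df)) abort("missing values in the design columns")
  tab <- table(df$subj, df$A, df$B)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    lab <- apply(bad, 1, function(i)
      paste(dimnames(tab)[[1]][i[1]], dimnames(tab)[[2]][i[2]],
            dimnames(tab)[[3]][i[3]], sep = "/"))
    abort(paste("unbalanced design; cells not observed exactly once:",
                paste(head(lab, 5), collapse = ", ")))
  }

  fit <- aov(y ~ A * B + Error(subj / (A * B)), data = df)
  sm <- summary(fit)
  pick <- function(stratum, term) {
    st <- sm[[stratum]]
    if (is.null(st)) return(NULL)
    tb <- st[[1]]
    i <- match(term, trimws(rownames(tb)))
    if (is.na(i)) return(NULL)
    res <- tb[nrow(tb), ]  # Residuals row
    ss_e <- res[["Sum Sq"]]; df_e <- res[["Df"]]
    ss <- tb[i, "Sum Sq"]; dfn <- tb[i, "Df"]
    if (is.na(tb[i, "F value"])) {
      # degenerate stratum (zero residual variance): report F by convention
      f <- if (ss <= .Machine$double.eps^0.5) 0 else Inf
      p <- if (f == 0) 1 else 0
    } else {
      f <- tb[i, "F value"]; p <- tb[i, "Pr(>F)"]
      if (ss <= .Machine$double.eps^0.5) { f <- 0; p <- 1 }
    }
    tibble(term = term, df_num = dfn, df_den = df_e, ss = ss, F = f, p = p)
  }
  effects <- dplyr::bind_rows(pick("Error: subj:A", "A"),
                              pick("Error: subj:B", "B"),
                              pick("Error: subj:A:B", "A:B"))

  lev_a <- levels(df$A); lev_b <- levels(df$B)
  contrasts <- NULL
  if (length(lev_a) == 2) {
    contrasts <- purrr::map_dfr(lev_b, function(bl) {
      sub <- df[df$B == bl, ]
      wide <- tidyr::pivot_wider(sub[, c("subj", "A", "y")],
                                 names_from = "A", values_from = "y")
      d <- wide[[lev_a[2]]] - wide[[lev_a[1]]]
      if (sd(d) == 0) {
        tt <- list(statistic = if (mean(d) == 0) 0 else Inf,
                   p.value = if (mean(d) == 0) 1 else 0)
      } else {
        tt <- stats::t.test(d)
      }
      tibble(level = bl,
             contrast = paste(lev_a[2], "-", lev_a[1]),
             estimate = mean(d),
             t = unname(tt$statistic), p = tt$p.value)
    })
    contrasts$p_sidak <- sidak_adjust(contrasts$p, length(lev_b))
    contrasts$stars <- p_stars(contrasts$p_sidak)
  }
  structure(list(effects = effects, contrasts = contrasts,
                 factors = list(a = a, b = b, subject = subject),
                 n_subjects = nlevels(df$subj)),
            class = "rm_anova")
}

#' @method print rm_anova
#' @export
print.rm_anova <- function(x, ...) {
  cat("<rm_anova> within-subject two-way decomposition\n")
  print(as.data.frame(x$effects), row.names = FALSE)
  if (!is.null(x$contrasts)) {
    cat("Sidak pairwise contrasts:\n")
    print(as.data.frame(x$contrasts), row.names = FALSE)
  }
  invisible(x)
}

#' @export
tidy.rm_anova <- function(x, ...) x$effects

#' @export
glance.rm_anova <- function(x, ...) {
  tibble(n_subjects = x$n_subjects,
         p_interaction = x$effects$p[x$effects$term == "A:B"])
}

#' Penetrance summary with pairwise Fisher tests and BH correction
#'
#' Per-genotype penetrance (mistargeted / total antennal lobes),
#' per-glomerulus mis-innervation frequencies with destinations above
#' the strict `primary_threshold` flagged primary, and all pairwise
#' genotype comparisons as two-sided Fisher exact tests on
#' mistargeted-vs-not 2x2 tables, BH-adjusted as one family.
#'
#' @param clones list with `records` (and optionally `glomeruli`) as
#'   produced by [gen_clone_table()] / [read_clone_table()]
#' @param primary_threshold strict frequency threshold for a "primary"
#'   mistargeting destination (the >20% convention)
#' @return list with `penetrance`, `destinations` (NULL without
#'   glomerulus tallies) and `pairwise` (NULL with < 2 genotypes)
#' @export
penetrance_summary <- function(clones, primary_threshold = 0.20) {
  recs <- clones$records
  pen <- dplyr::mutate(
    dplyr::select(recs, "genotype", "n_total", "n_mistargeted"),
    penetrance = .data$n_mistargeted / .data$n_total)

  destinations <- NULL
  if (!is.null(clones$glomeruli) && nrow(clones$glomeruli) > 0) {
    destinations <- dplyr::mutate(
      dplyr::left_join(clones$glomeruli,
                       dplyr::select(pen, "genotype", "n_total"),
                       by = "genotype"),
      frequency = .data$glomerulus_count / .data$n_total,
      primary = .data$frequency > primary_threshold)
  }

  pairwise <- NULL
  if (nrow(pen) >= 2) {
    combos <- utils::combn(pen$genotype, 2, simplify = FALSE)
    pairwise <- purrr::map_dfr(combos, function(gp) {
      r1 <- pen[pen$genotype == gp[1], ]; r2 <- pen[pen$genotype == gp[2], ]
      tb <- matrix(c(r1$n_mistargeted, r1$n_total - r1$n_mistargeted,
                     r2$n_mistargeted, r2$n_total - r2$n_mistargeted),
                   nrow = 2, byrow = TRUE)
      tibble(comparison = paste(gp, collapse = " vs "),
             statistic = (r1$n_mistargeted / r1$n_total) -
               (r2$n_mistargeted / r2$n_total),
             p = fisher_exact_2x2(tb), method = "fisher_exact_2x2")
    })
    pairwise$p_adj <- bh_fdr(pairwise$p)
    pairwise$stars <- p_stars(pairwise$p_adj)
  }
  list(penetrance = pen, destinations = destinations, pairwise = pairwise)
}

#' Pearson correlation between two sets of glomerular frequencies
#'
#' @param freq_a,freq_b per-glomerulus mis-innervation frequencies over
#'   the same glomeruli: either aligned numeric vectors, or named
#'   vectors (matched by name)
#' @return Pearson r; `NA` (with warning) on zero variance
#' @export
frequency_correlation <- function(freq_a, freq_b) {
  if (!is.null(names(freq_a)) && !is.null(names(freq_b))) {
    if (!setequal(names(freq_a), names(freq_b)))
      abort("frequency vectors cover different glomeruli")
    freq_b <- freq_b[names(freq_a)]
  }
  pearson_r(as.numeric(freq_a), as.numeric(freq_b))
}

#' Write a stats table in the standard CSV layout
#' @param stats tibble with columns comparison, statistic, p, p_adj,
#'   method (and optionally stars)
#' @param path output CSV
#' @export
write_stats_csv <- function(stats, path) {
  if (!"stars" %in% names(stats)) stats$stars <- p_stars(stats$p_adj)
  readr::write_csv(stats, path)
  invisible(path)
}
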