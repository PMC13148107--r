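# Synthetic clone-scoring tables: per genotype, each antennal-lobe clone
# is scored mistargeted with the configured true penetrance; mistargeted
# clones then mis-innervate each glomerulus independently with its
# configured probability (at least one destination per mistargeted
# clone), so per-glomerulus tallies are always consistent with totals.

#' Simulate clone-scoring (penetrance) tables
#'
#' @param genotypes list of `list(name=, n_clones=, true_penetrance=,
#'   glom_probs=)` where `glom_probs` is a named vector of per-glomerulus
#'   mis-innervation probabilities given a mistargeted clone
#' @param seed integer seed
#' @return list with `records` (tibble: genotype, n_total,
#'   n_mistargeted, penetrance) and `glomeruli` (long tibble: genotype,
#'   glomerulus, glomerulus_count)
#' @export
gen_clone_table <- function(genotypes, seed = 1) {
  for (g in genotypes) {
    if (!all(c("name", "n_clones", "true_penetrance") %in% names(g)))
      abort("each genotype needs name, n_clones and true_penetrance")
    if (g$true_penetrance < 0 || g$true_penetrance > 1)
      abort("true_penetrance must be in [0, 1]")
    if (!is.null(g$glom_probs) && (any(g$glom_probs < 0) || any(g$glom_probs > 1)))
      abort("glom_probs must be in [0, 1]")
  }
  with_seed(seed, {
    recs <- list(); gloms <- list()
    for (g in genotypes) {
      n_mis <- rbinom(1, g$n_clones, g$true_penetrance)
      recs[[g$name]] <- tibble(genotype = g$name, n_total = g$n_clones,
                               n_mistargeted = n_mis,
                               penetrance = n_mis / g$n_clones)
      q <- g$glom_probs
      if (!is.null(q) && length(q) > 0) {
        tal <- setNames(integer(length(q)), names(q))
        for (k in seq_len(n_mis)) {
          hit <- runif(length(q)) < q
          if (!any(hit)) hit[which.max(q)] <- TRUE  # every mistargeted clone lands somewhere
          tal <- tal + hit
        }
        gloms[[g$name]] <- tibble(genotype = g$name, glomerulus = names(q),
                                  glomerulus_count = as.integer(tal))
      }
    }
    list(records = dplyr::bind_rows(recs), glomeruli = dplyr::bind_rows(gloms))
  })
}

#' Write / read clone tables as CSV
#'
#' Long layout with the genotype-level totals repeated on every
#' glomerulus row: `genotype,n_total,n_mistargeted,glomerulus,
#' glomerulus_count`. Genotypes without glomerulus tallies get a single
#' row with empty glomerulus fields.
#'
#' @param clones output of [gen_clone_table()]
#' @param path CSV path
#' @return the path, invisibly; `read_clone_table` returns the
#'   `gen_clone_table()` list form
#' @export
write_clone_table <- function(clones, path) {
  recs <- dplyr::select(clones$records, "genotype", "n_total", "n_mistargeted")
  if (!is.null(clones$glomeruli) && nrow(clones$glomeruli) > 0) {
    out <- dplyr::full_join(recs, clones$glomeruli, by = "genotype")
  } else {
    out <- dplyr::mutate(recs, glomerulus = NA_character_,
                         glomerulus_count = NA_integer_)
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_clone_table
#' @export
read_clone_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          genotype = readr::col_character(),
                          glomerulus = readr::col_character()))
  recs <- dplyr::distinct(df, .data$genotype, .data$n_total, .data$n_mistargeted)
  recs$penetrance <- recs$n_mistargeted / recs$n_total
  gl <- dplyr::filter(df, !is.na(.data$glomerulus))
  list(records = as_tibble(recs),
       glomeruli = as_tibble(dplyr::select(gl, "genotype", "glomerulus",
                                           "glomerulus_count")))
}
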