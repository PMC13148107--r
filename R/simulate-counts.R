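# Synthetic single-cell count matrices with planted anti-correlated
# partners. The generator emulates SMART-seq2 plate data aggregated over
# projection-neuron subtypes: negative-binomial counts around
# subtype-specific gene means scaled to a per-cell library size, uniform
# dropout, mitochondrial genes ("mt:" prefix) and ERCC spike-ins
# ("ERCC-" prefix) at configured count fractions, and a curated
# cell-surface-molecule (CSM) gene set containing the target and any
# planted partners.

#' Configuration for the synthetic single-cell generator
#'
#' @param n_subtypes number of neuronal subtypes (pseudo-bulk groups)
#' @param cells_per_subtype cells simulated per subtype
#' @param n_genes total gene universe size, including mito/ERCC/markers
#' @param n_csms number of cell-surface-molecule genes (includes the
#'   target gene `caps`)
#' @param planted_pairs list of `list(target=, partner=, strength=)`;
#'   `strength` in \[0,1\] interpolates the partner's subtype-mean
#'   profile between an independent random profile (0) and an exact
#'   decreasing affine transform of the target's (1)
#' @param nb_dispersion negative-binomial `size`; counts have variance
#'   `mu + mu^2/size`
#' @param dropout_rate probability that any given count is zeroed,
#'   independently of its magnitude
#' @param library_size_mean expected total counts per cell
#' @param library_size_sdlog log-normal sd of per-cell library scaling
#' @param mito_fraction_range,ercc_fraction_range per-cell count
#'   fractions for mitochondrial genes and spike-ins, drawn uniformly
#' @param n_mito,n_ercc,n_markers sizes of the special gene groups
#' @param subtype_profile_sd log-scale sd of across-subtype variation in
#'   gene means (drives the subtype structure the screen exploits)
#' @param planted_mean_range range of the planted target's subtype mean
#'   counts (at reference library size), drawn uniformly; a moderate
#'   range keeps both the log-intensity and the detection-fraction
#'   profiles informative so the reflected partner profile is
#'   recoverable in the space the screen actually measures
#' @param base_means optional genes x subtypes matrix of expected counts
#'   (at unit library scaling) overriding the random profile draw; row
#'   names must be gene ids
#' @param seed integer seed; identical configs give bit-identical output
#'
#' @return a validated `sim_config` list
#' @export
sim_config <- function(n_subtypes = 30, cells_per_subtype = 30,
                       n_genes = 2000, n_csms = 60,
                       planted_pairs = list(list(target = "caps",
                                                 partner = "CSM002",
                                                 strength = 1)),
                       nb_dispersion = 2, dropout_rate = 0.15,
                       library_size_mean = 5e5, library_size_sdlog = 0.25,
                       mito_fraction_range = c(0.005, 0.04),
                       ercc_fraction_range = c(0.005, 0.02),
                       n_mito = 10, n_ercc = 20, n_markers = 5,
                       subtype_profile_sd = 1.2,
                       planted_mean_range = c(0.5, 10),
                       base_means = NULL, seed = 1L) {
  cfg <- list(n_subtypes = as.integer(n_subtypes),
              cells_per_subtype = as.integer(cells_per_subtype),
              n_genes = as.integer(n_genes), n_csms = as.integer(n_csms),
              planted_pairs = planted_pairs,
              nb_dispersion = nb_dispersion, dropout_rate = dropout_rate,
              library_size_mean = library_size_mean,
              library_size_sdlog = library_size_sdlog,
              mito_fraction_range = mito_fraction_range,
              ercc_fraction_range = ercc_fraction_range,
              n_mito = as.integer(n_mito), n_ercc = as.integer(n_ercc),
              n_markers = as.integer(n_markers),
              subtype_profile_sd = subtype_profile_sd,
              planted_mean_range = planted_mean_range,
              base_means = base_means, seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_subtypes, cells_per_subtype, n_genes, n_csms) < 1))
      abort("all counts in sim_config must be positive")
    if (dropout_rate < 0 || dropout_rate > 1)
      abort("dropout_rate must be in [0, 1]")
    if (any(mito_fraction_range < 0) || any(mito_fraction_range > 1) ||
        any(ercc_fraction_range < 0) || any(ercc_fraction_range > 1))
      abort("fraction ranges must lie in [0, 1]")
    if (nb_dispersion <= 0 || library_size_mean <= 0)
      abort("nb_dispersion and library_size_mean must be positive")
    if (n_genes < n_csms + n_mito + n_ercc + n_markers)
      abort("n_genes too small for the special gene groups")
  })
  for (pp in cfg$planted_pairs) {
    if (!all(c("target", "partner", "strength") %in% names(pp)))
      abort("each planted pair needs target, partner and strength")
    if (pp$strength < 0 || pp$strength > 1)
      abort("planted strength must be in [0, 1]")
    if (pp$target == pp$partner)
      abort("planted target and partner must be distinct genes")
  }
  structure(cfg, class = "sim_config")
}

#' Gene universe implied by a sim_config
#'
#' CSM ids are `caps`, `CSM002`, ..., markers are canonical fly neuronal
#' genes, mitochondrial genes carry the `mt:` prefix and spike-ins the
#' `ERCC-` prefix; the remainder are background genes.
#'
#' @param config a [sim_config()]
#' @return gene metadata tibble with flag columns
#' @export
sim_gene_table <- function(config) {
  markers <- c("elav", "nSyb", "Syt1", "brp", "CadN")[seq_len(config$n_markers)]
  csms <- c("caps", sprintf("CSM%03d", seq_len(config$n_csms))[-1])
  mito <- sprintf("mt:gene%02d", seq_len(config$n_mito))
  ercc <- sprintf("ERCC-%05d", seq_len(config$n_ercc))
  n_bg <- config$n_genes - length(markers) - length(csms) -
    length(mito) - length(ercc)
  bg <- sprintf("gene%05d", seq_len(n_bg))
  tibble(
    gene_id = c(csms, markers, bg, mito, ercc),
    is_csm = c(rep(TRUE, length(csms)), rep(FALSE, config$n_genes - length(csms))),
    is_marker = c(rep(FALSE, length(csms)), rep(TRUE, length(markers)),
                  rep(FALSE, config$n_genes - length(csms) - length(markers))),
    is_mito = startsWith(c(csms, markers, bg, mito, ercc), "mt:"),
    is_ercc = startsWith(c(csms, markers, bg, mito, ercc), "ERCC-")
  )
}

#' Simulate a single-cell count matrix with known ground truth
#'
#' Draws, for every cell, negative-binomial counts around subtype-specific
#' gene means scaled to a per-cell library size, then zeroes each entry
#' independently with the configured dropout probability. Planted partner
#' genes have subtype-mean profiles interpolated towards an exact
#' decreasing affine transform of their target's profile, so at
#' `strength = 1` the pre-sampling Pearson correlation between the two
#' mean vectors is exactly -1.
#'
#' @param config a [sim_config()]
#' @return list with elements `matrix` (a [count_matrix()]) and `truth`
#'   (gene-by-subtype expected counts, planted pair ids, subtype labels,
#'   and the config used)
#' @export
gen_sc_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sim_gene_table(config)
  ids <- genes$gene_id
  for (pp in config$planted_pairs) {
    if (!all(c(pp$target, pp$partner) %in% ids))
      abort(sprintf("planted pair (%s, %s) references unknown gene(s)",
                    pp$target, pp$partner))
  }
  subtypes <- sprintf("PN%02d", seq_len(config$n_subtypes))

  with_seed(config$seed, {
    M <- sim_mean_profiles(config, genes, subtypes)

    n_cells <- config$n_subtypes * config$cells_per_subtype
    cell_sub <- rep(subtypes, each = config$cells_per_subtype)
    cell_ids <- sprintf("cell%04d", seq_len(n_cells))

    sdlog <- config$library_size_sdlog
    scaling <- if (sdlog > 0)
      exp(rnorm(n_cells, -sdlog^2 / 2, sdlog)) else rep(1, n_cells)
    f_m <- runif(n_cells, config$mito_fraction_range[1], config$mito_fraction_range[2])
    f_e <- runif(n_cells, config$ercc_fraction_range[1], config$ercc_fraction_range[2])

    direct <- !is.null(config$base_means)   # base_means IS the expected count matrix
    cellular <- !genes$is_mito & !genes$is_ercc
    fm0 <- mean(config$mito_fraction_range)
    fe0 <- mean(config$ercc_fraction_range)
    counts <- matrix(0L, n_cells, config$n_genes,
                     dimnames = list(cell_ids, ids))
    for (c_i in seq_len(n_cells)) {
      mu <- scaling[c_i] * M[, cell_sub[c_i]]
      if (!direct) {   # per-cell wiggle of the mito / spike-in fractions
        mu[cellular] <- mu[cellular] * (1 - f_m[c_i] - f_e[c_i]) / (1 - fm0 - fe0)
        if (fm0 > 0) mu[genes$is_mito] <- mu[genes$is_mito] * f_m[c_i] / fm0
        if (fe0 > 0) mu[genes$is_ercc] <- mu[genes$is_ercc] * f_e[c_i] / fe0
      }
      x <- rnbinom(config$n_genes, mu = mu, size = config$nb_dispersion)
      if (config$dropout_rate > 0)
        x[runif(config$n_genes) < config$dropout_rate] <- 0L
      counts[c_i, ] <- x
    }

    cm <- count_matrix(counts, genes,
                       tibble(cell_id = cell_ids, subtype = cell_sub))
    truth <- structure(list(
      base_profiles = M, gene_means = M, subtypes = subtypes,
      planted_pairs = config$planted_pairs,
      genes = genes, config = config), class = "sim_truth")
    list(matrix = cm, truth = truth)
  })
}

# Subtype-mean profiles in absolute expected-count units (at unit
# library scaling and midpoint mito/ERCC fractions). Gene groups are
# rescaled once, globally, so that an average cell's totals match the
# configured library size and count fractions; planted pairs are then
# written in absolute units so their means sit where both the log
# intensity and the detection fraction remain informative.
sim_mean_profiles <- function(config, genes, subtypes) {
  n_g <- config$n_genes
  if (!is.null(config$base_means)) {
    M <- config$base_means
    if (is.null(rownames(M)) || !setequal(rownames(M), genes$gene_id))
      abort("base_means row names must match the gene universe")
    M <- M[genes$gene_id, , drop = FALSE]
    colnames(M) <- subtypes
    return(M)
  }
  base <- rlnorm(n_g, meanlog = 1.5, sdlog = 1.5)
  base[genes$is_csm] <- rlnorm(sum(genes$is_csm), meanlog = 3, sdlog = 0.8)
  M <- base * matrix(exp(rnorm(n_g * length(subtypes), 0, config$subtype_profile_sd)),
                     n_g, length(subtypes))
  M[genes$is_marker, ] <- 200          # flat, broadly expressed markers
  # mito content and spike-in load are cell-quality properties, not
  # subtype identity: keep their expected fractions flat across subtypes
  M[genes$is_mito, ] <- base[genes$is_mito]
  M[genes$is_ercc, ] <- base[genes$is_ercc]
  rownames(M) <- genes$gene_id
  colnames(M) <- subtypes

  fm0 <- mean(config$mito_fraction_range)
  fe0 <- mean(config$ercc_fraction_range)
  L <- config$library_size_mean
  cellular <- !genes$is_mito & !genes$is_ercc
  M[cellular, ] <- M[cellular, ] *
    (L * (1 - fm0 - fe0) / mean(colSums(M[cellular, , drop = FALSE])))
  M[genes$is_mito, ] <- M[genes$is_mito, ] *
    (L * fm0 / mean(colSums(M[genes$is_mito, , drop = FALSE])))
  M[genes$is_ercc, ] <- M[genes$is_ercc, ] *
    (L * fe0 / mean(colSums(M[genes$is_ercc, , drop = FALSE])))

  for (pp in config$planted_pairs) {
    v <- sort(runif(length(subtypes), config$planted_mean_range[1],
                    config$planted_mean_range[2]))[sample.int(length(subtypes))]
    M[pp$target, ] <- v
    reflected <- (max(v) + min(v)) - v            # exact negative affine, > 0
    own <- M[pp$partner, ]
    M[pp$partner, ] <- pp$strength * reflected + (1 - pp$strength) * own
  }
  M
}

# Evaluate code under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
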