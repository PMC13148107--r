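# The anti-correlation screen: CSM gating, dual-matrix Pearson scores,
# the integrated score, ranking, and ipTM ingestion.

# profiles with controllable target/candidate columns in both matrices
two_col_profiles <- function(tm, tf, cm, cf, extra = 0) {
  n <- length(tm)
  genes <- c("caps", "cand", sprintf("d%02d", seq_len(extra)))
  mean_m <- cbind(tm, cm)
  frac_m <- cbind(tf, cf)
  if (extra > 0) {
    mean_m <- cbind(mean_m, matrix(runif(n * extra, 0, 6), n))
    frac_m <- cbind(frac_m, matrix(runif(n * extra), n))
  }
  dimnames(mean_m) <- dimnames(frac_m) <-
    list(sprintf("T%02d", seq_len(n)), genes)
  subtype_profiles(mean_m, frac_m, setNames(rep(10L, n), rownames(mean_m)))
}

test_that("CSM gate applies strict thresholds within a single subtype", {
  mean_m <- rbind(A = c(3.5, 3.0, 3.5, 2.0),
                  B = c(1.0, 3.0, 1.0, 3.5))
  frac_m <- rbind(A = c(0.8, 0.9, 0.1, 0.9),
                  B = c(0.2, 0.9, 0.6, 0.4))
  colnames(mean_m) <- colnames(frac_m) <- c("pass", "boundary", "split", "split2")
  p <- subtype_profiles(mean_m, frac_m, c(A = 5L, B = 5L))
  kept <- filter_csms(p, colnames(mean_m))
  expect_true("pass" %in% kept)        # 3.5 & 0.8 in subtype A
  expect_false("boundary" %in% kept)   # mean exactly 3.0 everywhere: strict >
  expect_false("split" %in% kept)      # mean in A but fraction only in B
  expect_false("split2" %in% kept)
  # the disjoint reading admits the split genes
  kept2 <- filter_csms(p, colnames(mean_m), joint = FALSE)
  expect_true(all(c("pass", "split", "split2") %in% kept2))
  expect_error(filter_csms(p, character(0)), "empty")
})

test_that("pearson_r matches the product-moment formula and handles degeneracy", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(1:5, 10 - 2 * (1:5)), -1)
  set.seed(41)
  for (i in 1:25) {
    x <- rnorm(5); y <- rnorm(5)
    expect_equal(pearson_r(x, y), oracle_pearson(x, y))
  }
  expect_warning(r <- pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_true(is.na(r))
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("integrated score is the exact mean of the two coefficients", {
  set.seed(42)
  p <- two_col_profiles(tm = runif(6, 1, 6), tf = runif(6),
                        cm = runif(6, 1, 6), cf = runif(6), extra = 3)
  res <- anticorr_scores(p, "caps", setdiff(p$genes, "caps"))
  expect_equal(res$score, (res$r_cpm + res$r_frac) / 2)
  expect_true(all(abs(res$score) <= 1))
})

test_that("perfectly matching and perfectly inverse candidates hit the score bounds", {
  tm <- c(1, 3, 5, 2, 4); tf <- c(0.1, 0.5, 0.9, 0.3, 0.7)
  same <- anticorr_scores(two_col_profiles(tm, tf, tm, tf), "caps", "cand")
  expect_equal(same$score, 1)
  anti <- anticorr_scores(two_col_profiles(tm, tf, 10 - 2 * tm, 1 - tf),
                          "caps", "cand")
  expect_equal(anti$r_cpm, -1)
  expect_equal(anti$r_frac, -1)
  expect_equal(anti$score, -1)
})

test_that("zero-variance candidates carry NA and zero-variance targets error", {
  tm <- c(1, 3, 5); tf <- c(0.1, 0.5, 0.9)
  p <- two_col_profiles(tm, tf, cm = c(2, 2, 2), cf = c(0.5, 0.5, 0.5))
  res <- anticorr_scores(p, "caps", "cand")
  expect_true(is.na(res$score))
  p_flat <- two_col_profiles(c(2, 2, 2), tf, tm, tf)
  expect_error(anticorr_scores(p_flat, "caps", "cand"), "mean-expression")
})

test_that("ranking sorts ascending with lexicographic ties and respects top_k", {
  res <- tibble::tibble(gene_id = c("B", "A", "C", "D"),
                        r_cpm = c(-0.9, -0.9, 0.2, -0.5),
                        r_frac = c(-0.9, -0.9, 0.2, -0.5))
  res$score <- (res$r_cpm + res$r_frac) / 2
  res$passed_filter <- TRUE
  ranked <- rank_candidates(inversepair:::new_screen_result(res, "caps"),
                            top_k = 2)
  expect_equal(ranked$gene_id, c("A", "B"))   # tie broken lexicographically
  expect_equal(ranked$rank, 1:2)
  all4 <- rank_candidates(inversepair:::new_screen_result(res, "caps"),
                          top_k = 10)
  expect_equal(all4$rank, 1:4)
  expect_equal(all4$gene_id[4], "C")
})

test_that("undefined scores are excluded from ranking with a message", {
  res <- tibble::tibble(gene_id = c("A", "B"),
                        r_cpm = c(-0.5, NA), r_frac = c(-0.5, NA),
                        score = c(-0.5, NA), passed_filter = TRUE)
  expect_message(ranked <- rank_candidates(
    inversepair:::new_screen_result(res, "caps")), "excluded")
  expect_equal(ranked$gene_id, "A")
})

test_that("screen is invariant to gene and subtype order and mean shifts", {
  set.seed(43)
  n_sub <- 8
  mean_m <- matrix(runif(n_sub * 6, 0, 6), n_sub,
                   dimnames = list(sprintf("T%02d", 1:n_sub),
                                   c("caps", sprintf("c%d", 1:5))))
  frac_m <- matrix(runif(n_sub * 6), n_sub, dimnames = dimnames(mean_m))
  p1 <- subtype_profiles(mean_m, frac_m, setNames(rep(5L, n_sub), rownames(mean_m)))
  base <- anticorr_scores(p1, "caps", sprintf("c%d", 1:5))

  perm_g <- c("c3", "caps", "c5", "c1", "c4", "c2")
  perm_t <- sample(n_sub)
  p2 <- subtype_profiles(mean_m[perm_t, perm_g], frac_m[perm_t, perm_g],
                         setNames(rep(5L, n_sub), rownames(mean_m)[perm_t]))
  shuf <- anticorr_scores(p2, "caps", sprintf("c%d", 1:5))
  expect_equal(dplyr::arrange(tibble::as_tibble(shuf), gene_id)$score,
               dplyr::arrange(tibble::as_tibble(base), gene_id)$score)

  p3 <- subtype_profiles(mean_m + 7, frac_m, setNames(rep(5L, n_sub), rownames(mean_m)))
  shifted <- anticorr_scores(p3, "caps", sprintf("c%d", 1:5))
  expect_equal(shifted$r_cpm, base$r_cpm)
})

test_that("ipTM ingestion averages models and sorts descending", {
  tb <- tibble::tibble(gene_id = c("Ten-m", "side", "beat-Ia"),
                       model_1 = c(0.8, 0.3, 0.5),
                       model_2 = c(0.7, 0.35, 0.5),
                       model_3 = c(0.9, 0.25, 0.5),
                       model_4 = c(0.85, 0.3, 0.5),
                       model_5 = c(0.75, 0.3, 0.5))
  out <- ingest_iptm(tb)
  expect_equal(out$mean_iptm[out$gene_id == "Ten-m"], 0.80)
  expect_equal(out$gene_id[1], "Ten-m")
  expect_equal(out$n_models, c(5L, 5L, 5L))
  single <- ingest_iptm(tibble::tibble(gene_id = "x", model_1 = 0.62))
  expect_equal(single$mean_iptm, 0.62)
  expect_error(ingest_iptm(tibble::tibble(gene_id = "x", model_1 = 1.2)),
               "\\[0, 1\\]")
})

test_that("ipTM ordering equals a brute-force sort on random tables", {
  set.seed(44)
  for (i in 1:10) {
    tb <- tibble::tibble(gene_id = sprintf("g%02d", sample(20, 8)),
                         model_1 = runif(8), model_2 = runif(8),
                         model_3 = runif(8))
    out <- ingest_iptm(tb)
    means <- rowMeans(as.matrix(tb[, -1]))
    oracle <- tb$gene_id[order(-means, tb$gene_id)]
    expect_equal(out$gene_id, oracle)
  }
})

test_that("merged shortlist carries structure scores by gene id", {
  set.seed(45)
  p <- two_col_profiles(tm = runif(5, 1, 6), tf = runif(5),
                        cm = runif(5, 1, 6), cf = runif(5), extra = 4)
  iptm <- tibble::tibble(gene_id = c("cand", "d01"), model_1 = c(0.9, 0.2))
  out <- run_screen(p, "caps", setdiff(p$genes, "caps"),
                    min_mean = -1, min_frac = -1, iptm = iptm)
  merged <- out$shortlist
  expect_equal(merged$mean_iptm[merged$gene_id == "cand"], 0.9)
  expect_true(is.na(merged$mean_iptm[merged$gene_id == "d03"]))
})
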