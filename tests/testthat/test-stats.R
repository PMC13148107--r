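# Fisher exact tests, BH FDR, Sidak, repeated-measures ANOVA, and
# penetrance summaries.

test_that("Fisher p matches enumeration on canonical tables", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)),
               oracle_fisher_p(matrix(c(5, 5, 5, 5), 2)))
  # probabilities {1, 9, 9, 1}/20; the two extreme tables sum to 0.1
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2)), 0.1)
  expect_equal(fisher_exact_2x2(matrix(c(0, 4, 0, 7), 2)), 1)  # degenerate margin
})

test_that("Fisher p equals the enumeration oracle on random small tables", {
  set.seed(81)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab), oracle_fisher_p(tab),
                 tolerance = 1e-10)
  }
})

test_that("Fisher p is invariant to transposition and joint row/col swaps", {
  set.seed(82)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 5), 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_2x2(tab)
    expect_equal(fisher_exact_2x2(t(tab)), p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[2:1, 2:1]), p, tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(83)
  for (i in 1:10) {
    p <- runif(sample(3:12, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
  }
})

test_that("BH rejection sets match the classic step-up rule", {
  set.seed(84)
  q <- 0.1
  for (i in 1:10) {
    p <- c(runif(8, 0, 0.08), runif(8))
    adj <- bh_fdr(p)
    # classic rule: reject the k smallest where k = max{i: p(i) <= i q / m}
    m <- length(p); o <- order(p)
    k <- suppressWarnings(max(which(p[o] <= seq_len(m) * q / m)))
    classic <- rep(FALSE, m)
    if (is.finite(k)) classic[o[seq_len(k)]] <- TRUE
    expect_equal(adj <= q, classic)
  }
})

test_that("Sidak adjustment follows 1 - (1-p)^m", {
  expect_equal(sidak_adjust(0.2, 1), 0.2)
  expect_equal(sidak_adjust(0.01, 3), 0.029701)
  expect_equal(sidak_adjust(1, 7), 1)
  expect_true(all(sidak_adjust(c(0.1, 0.5), 4) >= c(0.1, 0.5)))
})

test_that("repeated-measures ANOVA handles degenerate fixtures by convention", {
  df <- expand.grid(experiment = c("s1", "s2", "s3"),
                    group = c("untransfected", "transfected"),
                    construct = c("wt", "mut"))
  df$intensity <- 5
  fit <- rm_two_way_anova(df)
  expect_equal(fit$effects$F, c(0, 0, 0))
  expect_equal(fit$effects$p, c(1, 1, 1))
  # pure subject effect is absorbed by blocking
  df$intensity <- rep(c(1, 2, 3), times = 4)
  fit2 <- rm_two_way_anova(df)
  expect_true(all(fit2$effects$F < 1e-10))
})

test_that("ANOVA F statistics equal a hand decomposition on a fixed design", {
  # 3 subjects x A(2) x B(2); within-subject strata
  df <- expand.grid(experiment = c("s1", "s2", "s3"),
                    group = c("g1", "g2"),
                    construct = c("b1", "b2"))
  df$intensity <- c(10, 12, 11,  20, 23, 22,   # b1: g1, g2
                    11, 13, 12,  14, 16, 15)   # b2: g1, g2
  fit <- rm_two_way_anova(df)
  y <- df$intensity
  gm <- mean(y)
  # cell and marginal means
  mean_a <- tapply(y, df$group, mean)
  mean_b <- tapply(y, df$construct, mean)
  mean_ab <- tapply(y, list(df$group, df$construct), mean)
  mean_s <- tapply(y, df$experiment, mean)
  mean_sa <- tapply(y, list(df$experiment, df$group), mean)
  mean_sb <- tapply(y, list(df$experiment, df$construct), mean)
  ss_a <- 6 * sum((mean_a - gm)^2)
  ss_b <- 6 * sum((mean_b - gm)^2)
  ss_ab <- 3 * sum((sweep(sweep(mean_ab, 1, mean_a), 2, mean_b) + gm)^2)
  ss_sa <- 2 * sum((mean_sa - outer(mean_s, mean_a, `+`) + gm)^2)
  ss_sb <- 2 * sum((mean_sb - outer(mean_s, mean_b, `+`) + gm)^2)
  f_a <- (ss_a / 1) / (ss_sa / 2)
  f_b <- (ss_b / 1) / (ss_sb / 2)
  eff <- fit$effects
  expect_equal(eff$F[eff$term == "A"], f_a)
  expect_equal(eff$F[eff$term == "B"], f_b)
  expect_equal(eff$ss[eff$term == "A:B"], ss_ab)
  expect_equal(eff$p[eff$term == "A"], stats::pf(f_a, 1, 2, lower.tail = FALSE))
  # Sidak contrasts: paired t within each construct, m = 2
  expect_equal(fit$contrasts$p_sidak, sidak_adjust(fit$contrasts$p, 2))
})

test_that("unbalanced designs are rejected with the offending cells listed", {
  df <- expand.grid(experiment = c("s1", "s2"),
                    group = c("g1", "g2"), construct = c("b1", "b2"))
  df$intensity <- rnorm(8)
  expect_error(rm_two_way_anova(df[-3, ]), "unbalanced")
})

test_that("penetrance summary computes rates, primary flags, and BH-corrected tests", {
  clones <- list(
    records = tibble::tibble(genotype = c("control", "mutA", "mutB"),
                             n_total = c(30L, 30L, 10L),
                             n_mistargeted = c(2L, 25L, 7L)),
    glomeruli = tibble::tibble(
      genotype = rep("mutA", 3),
      glomerulus = c("DA4l", "DL1", "VA2"),
      glomerulus_count = c(20L, 6L, 3L)))
  out <- penetrance_summary(clones)
  expect_equal(out$penetrance$penetrance, c(2 / 30, 25 / 30, 0.7))
  # 6/30 is exactly 0.20: NOT primary under the strict rule
  dest <- out$destinations
  expect_true(dest$primary[dest$glomerulus == "DA4l"])
  expect_false(dest$primary[dest$glomerulus == "DL1"])
  expect_false(dest$primary[dest$glomerulus == "VA2"])
  expect_equal(nrow(out$pairwise), 3)
  expect_equal(out$pairwise$p_adj, bh_fdr(out$pairwise$p))
  p_cm <- fisher_exact_2x2(matrix(c(2, 28, 25, 5), 2, byrow = TRUE))
  expect_equal(out$pairwise$p[1], p_cm)
  expect_equal(out$pairwise$stars, p_stars(out$pairwise$p_adj))
})

test_that("frequency correlation hits the exact bounds and matches the formula", {
  f <- c(DA4l = 0.8, DL1 = 0.3, VA2 = 0.1, DM6 = 0.5)
  expect_equal(frequency_correlation(f, f), 1)
  expect_equal(frequency_correlation(f, 1 - f), -1)
  set.seed(85)
  a <- runif(6); b <- runif(6)
  expect_equal(frequency_correlation(a, b), oracle_pearson(a, b))
  # name-matched alignment
  g <- f[c(3, 1, 4, 2)]
  expect_equal(frequency_correlation(f, g), 1)
  expect_error(frequency_correlation(f, c(x = 1, y = 2, z = 3, w = 4)),
               "different glomeruli")
})

test_that("clone-table generation respects degenerate penetrances and CSV round trips", {
  zero <- gen_clone_table(list(list(name = "g0", n_clones = 25,
                                    true_penetrance = 0)), seed = 86)
  expect_equal(zero$records$n_mistargeted, 0L)
  one <- gen_clone_table(list(list(name = "g1", n_clones = 25,
                                   true_penetrance = 1)), seed = 86)
  expect_equal(one$records$n_mistargeted, 25L)
  set.seed(1)
  mid <- gen_clone_table(list(list(name = "g", n_clones = 200,
                                   true_penetrance = 0.5,
                                   glom_probs = c(DA4l = 0.6, DL1 = 0.2))),
                         seed = 87)
  expect_lt(abs(mid$records$penetrance - 0.5), 3 * sqrt(0.25 / 200))
  expect_true(all(mid$glomeruli$glomerulus_count <= mid$records$n_mistargeted))
  path <- file.path(tmp_dir(), "clones.csv")
  write_clone_table(mid, path)
  back <- read_clone_table(path)
  expect_equal(back$records$n_mistargeted, mid$records$n_mistargeted)
  expect_equal(back$glomeruli$glomerulus_count, mid$glomeruli$glomerulus_count)
})
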