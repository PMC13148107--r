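# Independent brute-force oracles, kept deliberately naive (loops,
# enumeration, direct formulas) so they share no code path with the
# package implementations they check.

oracle_pearson <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  sum((x - xb) * (y - yb)) /
    sqrt(sum((x - xb)^2) * sum((y - yb)^2))
}

# two-sided Fisher p by full enumeration of tables with fixed margins:
# sum P(table) over tables whose probability <= P(observed) (1 + 1e-7
# relative tie tolerance)
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  a_min <- max(0, c1 - r2); a_max <- min(r1, c1)
  probs <- vapply(a_min:a_max, function(a)
    stats::dhyper(a, r1, r2, c1), numeric(1))
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exhaustive binned between-class-variance search
oracle_otsu <- function(img, n_bins = 256) {
  v <- as.vector(img)
  rng <- range(v)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  h <- numeric(n_bins)
  for (b in bin) h[b] <- h[b] + 1
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  best <- -Inf; best_cut <- NA
  for (k in seq_len(n_bins - 1)) {
    w0 <- sum(h[1:k]); w1 <- sum(h[(k + 1):n_bins])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:k] * centers[1:k]) / w0
    mu1 <- sum(h[(k + 1):n_bins] * centers[(k + 1):n_bins]) / w1
    s <- (w0 / length(v)) * (w1 / length(v)) * (mu0 - mu1)^2
    if (s > best) { best <- s; best_cut <- k }
  }
  breaks[best_cut + 1]
}

# BFS flood fill, 8-connected
oracle_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue) > 0) {
      q <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- q[1] + di; jj <- q[2] + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue <- c(queue, list(c(ii, jj)))
        }
      }
    }
  }
  lab
}

# BH step-up by the textbook formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# per-group means by explicit double loop
oracle_group_means <- function(values, groups) {
  out <- list()
  for (g in unique(groups)) {
    tot <- 0; n <- 0
    for (i in seq_along(values)) {
      if (groups[i] == g) { tot <- tot + values[i]; n <- n + 1 }
    }
    out[[as.character(g)]] <- tot / n
  }
  out
}

# rasterised disk mask in an nr x nc canvas
make_disk <- function(nr, nc, cy, cx, r) {
  m <- matrix(FALSE, nr, nc)
  for (j in seq_len(nc)) for (i in seq_len(nr))
    if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- TRUE
  m
}

# minimal normalized_matrix for profile tests, built from a dense
# log-value matrix (zeros stay zero so detection = value > 0)
make_normalized <- function(values, labels) {
  vals <- methods::as(Matrix::Matrix(values, sparse = TRUE), "CsparseMatrix")
  rownames(vals) <- sprintf("c%03d", seq_len(nrow(values)))
  colnames(vals) <- colnames(values) %||%
    sprintf("g%03d", seq_len(ncol(values)))
  structure(list(values = vals,
                 genes = tibble::tibble(gene_id = colnames(vals)),
                 cells = tibble::tibble(cell_id = rownames(vals),
                                        subtype = labels),
                 unit = "log2(CPM+1)"),
            class = "normalized_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tmp_dir <- function() {
  d <- tempfile("ivp")
  dir.create(d)
  d
}

# small subtype_profiles object from explicit matrices
make_profiles <- function(mean_m, frac_m = NULL) {
  if (is.null(frac_m))
    frac_m <- matrix(pmin(1, pmax(0, mean_m / max(mean_m))),
                     nrow(mean_m), dimnames = dimnames(mean_m))
  if (is.null(rownames(mean_m)))
    rownames(mean_m) <- rownames(frac_m) <- sprintf("T%02d", seq_len(nrow(mean_m)))
  if (is.null(colnames(mean_m)))
    colnames(mean_m) <- colnames(frac_m) <- sprintf("g%03d", seq_len(ncol(mean_m)))
  subtype_profiles(mean_m, frac_m,
                   stats::setNames(rep(10L, nrow(mean_m)), rownames(mean_m)))
}
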