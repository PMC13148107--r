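# Low-level image primitives: Otsu histogram thresholding, 8-connected
# component labelling, binary disk dilation, and a 4-direction Crofton
# perimeter estimator. Images are plain numeric matrices (rows = y);
# masks are logical matrices.

# out[i, j] = M[i - di, j - dj], padded with `fill`
shift_matrix <- function(M, di, dj, fill = 0) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(fill, nr, nc)
  src_r <- max(1, 1 - di):min(nr, nr - di)
  src_c <- max(1, 1 - dj):min(nc, nc - dj)
  if (length(src_r) < 1 || length(src_c) < 1) return(out)
  out[src_r + di, src_c + dj] <- M[src_r, src_c]
  out
}

#' Otsu threshold of a grayscale image
#'
#' Bins the observed intensity range into `n_bins` equal-width bins and
#' exhaustively searches the cut-point maximizing the between-class
#' variance `w0 * w1 * (mu0 - mu1)^2`; ties take the lowest cut. The
#' returned threshold is the bin edge at the chosen cut, so the
#' foreground mask is `channel > threshold`.
#'
#' @param channel 2-D numeric matrix with at least two distinct values
#' @param n_bins histogram bins (256 matches 8-bit provenance)
#' @return the threshold (scalar)
#' @export
otsu_threshold <- function(channel, n_bins = 256) {
  v <- as.vector(channel)
  lo <- min(v); hi <- max(v)
  if (lo == hi) abort("constant image: Otsu threshold undefined")
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  bin <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  h <- tabulate(bin, n_bins)
  p <- h / sum(h)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)[-n_bins]
  m0 <- cumsum(p * centers)[-n_bins]
  mu_t <- sum(p * centers)
  w1 <- 1 - w0
  sigma_b <- ifelse(w0 > 0 & w1 > 0, (mu_t * w0 - m0)^2 / (w0 * w1), 0)
  cut <- which.max(sigma_b)       # first maximum on ties
  breaks[cut + 1]
}

#' Label 8-connected foreground components
#'
#' Iterative minimum-label propagation over the 8-neighbourhood until a
#' fixed point, then relabelling to consecutive integers 1..k in
#' first-pixel (column-major) order.
#'
#' @param mask logical matrix
#' @return integer matrix of the same shape; 0 = background
#' @export
label_components <- function(mask) {
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  L <- matrix(Inf, nr, nc)
  L[mask] <- which(mask)          # unique provisional labels
  nbrs <- expand.grid(di = -1:1, dj = -1:1)
  nbrs <- nbrs[!(nbrs$di == 0 & nbrs$dj == 0), ]
  repeat {
    Lmin <- L
    for (k in seq_len(nrow(nbrs)))
      Lmin <- pmin(Lmin, shift_matrix(L, nbrs$di[k], nbrs$dj[k], fill = Inf))
    Lmin[!mask] <- Inf
    if (identical(Lmin, L)) break
    L <- Lmin
  }
  out <- matrix(0L, nr, nc)
  if (any(mask)) {
    lin <- which(mask)                    # column-major order
    ids <- L[lin]
    out[lin] <- match(ids, unique(ids))   # consecutive, first-occurrence order
  }
  out
}

#' Dilate a binary mask with a disk structuring element
#'
#' @param mask logical matrix
#' @param r_px disk radius in pixels (0 returns the mask unchanged)
#' @return logical matrix
#' @export
dilate_disk <- function(mask, r_px) {
  mask <- mask > 0
  if (r_px < 1) return(mask)
  out <- mask
  for (di in -r_px:r_px) {
    span <- floor(sqrt(r_px^2 - di^2))
    for (dj in -span:span) {
      if (di == 0 && dj == 0) next
      out <- out | shift_matrix(mask, di, dj, fill = FALSE) > 0
    }
  }
  out
}

#' Crofton perimeter of a binary mask (4 directions)
#'
#' Integral-geometry perimeter estimate from the histogram of 2x2 pixel
#' configurations. Unlike boundary-pixel counting it is close to the
#' true continuous perimeter for rasterised disks, which is what makes
#' the `4*pi*area/perimeter^2` circularity gate usable.
#'
#' @param mask logical matrix
#' @return estimated perimeter in pixel units (total over all objects)
#' @export
crofton_perimeter <- function(mask) {
  I <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  I[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- as.numeric(mask > 0)
  XF <- I + 4 * shift_matrix(I, 0, 1) + 2 * shift_matrix(I, 1, 0) +
    8 * shift_matrix(I, 1, 1)
  h <- tabulate(as.vector(XF) + 1, 16)   # configurations 0..15
  s2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2), 0,
             pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2), pi / 4, pi / 2,
             pi / (4 * s2), pi / (4 * s2), pi / 4, pi / 2, 0, 0)
  sum(coefs * h)
}

#' Circularity of a binary mask
#'
#' `4 * pi * area / perimeter^2` with the Crofton perimeter; 1 for an
#' ideal disk, near 0 for a line.
#'
#' @param mask logical matrix containing a single object
#' @return circularity (>= 0)
#' @export
mask_circularity <- function(mask) {
  a <- sum(mask > 0)
  p <- crofton_perimeter(mask)
  if (p == 0) return(0)
  4 * pi * a / p^2
}
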