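# Spatial expression quantification: wide line profiles along an axis
# (e.g. dorsomedial-ventrolateral), min-max normalisation per lobe and
# channel, resampled averaging with SEM, and glomerular ROI intensities
# normalised to a reference (Ncad) channel.

#' Wide line profile with bilinear sampling
#'
#' Samples the channel at unit steps along the segment from `start` to
#' `end`; at each step the value is the mean over `width_px` evenly
#' spaced perpendicular offsets centred on the line (bilinear
#' interpolation at every sample point).
#'
#' @param channel 2-D matrix
#' @param start,end `c(x, y)` endpoints in pixel coordinates (x = column,
#'   y = row, 1-based)
#' @param width_px profile width in pixels (>= 1)
#' @return tibble with columns `distance_px` and `value`
#' @export
line_profile <- function(channel, start, end, width_px = 10) {
  if (width_px < 1) abort("width_px must be >= 1")
  dx <- end[1] - start[1]; dy <- end[2] - start[2]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) abort("zero-length line")
  ux <- dx / len; uy <- dy / len          # along-line unit vector
  px <- -uy; py <- ux                     # perpendicular unit vector
  n_steps <- round(len)
  t_seq <- seq(0, len, length.out = n_steps + 1)
  offsets <- if (width_px == 1) 0 else
    seq(-(width_px - 1) / 2, (width_px - 1) / 2, length.out = width_px)

  xs <- outer(start[1] + t_seq * ux, offsets * px, `+`)
  ys <- outer(start[2] + t_seq * uy, offsets * py, `+`)
  if (any(xs < 1 | xs > ncol(channel) | ys < 1 | ys > nrow(channel)))
    abort("profile samples fall outside the image; shorten the line or width")
  vals <- pracma::interp2(x = seq_len(ncol(channel)), y = seq_len(nrow(channel)),
                          Z = channel, xp = as.vector(xs), yp = as.vector(ys))
  prof <- rowMeans(matrix(vals, nrow = length(t_seq)))
  tibble(distance_px = t_seq, value = prof)
}

#' Min-max normalise a raw profile
#'
#' `(v - min) / (max - min)`; positions are rescaled to \[0, 1\].
#' Degenerate (constant) profiles are flagged and returned as all-zero
#' with a warning rather than dividing by zero.
#'
#' @param profile tibble from [line_profile()] (columns `distance_px`,
#'   `value`)
#' @return a `profile_record` tibble with `position` in \[0,1\],
#'   normalised `value`, and attribute `degenerate`
#' @export
minmax_normalize <- function(profile) {
  if (nrow(profile) < 2) abort("profile needs at least 2 samples")
  v <- profile$value
  degenerate <- max(v) == min(v)
  if (degenerate) {
    warn("degenerate profile (max == min); returning zeros")
    vn <- rep(0, length(v))
  } else {
    vn <- (v - min(v)) / (max(v) - min(v))
  }
  out <- tibble(position = (profile$distance_px - min(profile$distance_px)) /
                  diff(range(profile$distance_px)),
                value = vn)
  attr(out, "degenerate") <- degenerate
  out
}

#' Average normalised profiles across replicates
#'
#' Linearly resamples every profile to `n_points` positions over
#' \[0, 1\], then reports the pointwise mean and standard error
#' (`sd / sqrt(n)`).
#'
#' @param profiles list of `profile_record` tibbles (>= 2)
#' @param n_points resampling grid size
#' @return tibble with `position`, `mean`, `sem`, `n`
#' @export
average_profiles <- function(profiles, n_points = 100) {
  if (length(profiles) < 2) abort("need at least 2 profiles to average")
  grid <- seq(0, 1, length.out = n_points)
  mat <- vapply(profiles, function(p)
    approx(p$position, p$value, xout = grid)$y, numeric(n_points))
  tibble(position = grid,
         mean = rowMeans(mat),
         sem = apply(mat, 1, sd) / sqrt(length(profiles)),
         n = length(profiles))
}

#' Reference-normalised glomerular ROI intensities
#'
#' Per labelled ROI (manually segmented glomeruli supplied as a label
#' matrix), the ratio of the channel's mean intensity to the reference
#' channel's mean intensity -- a ratio of means, correcting
#' depth-dependent attenuation. ROIs whose reference mean is zero are
#' flagged invalid.
#'
#' @param channel,reference_channel 2-D matrices of equal shape
#' @param roi_labels integer label matrix (0 = background); names can be
#'   attached via `roi_names`
#' @param roi_names optional tibble with columns `label`, `glomerulus`
#' @return tibble: glomerulus, label, mean_channel, mean_reference,
#'   normalized, valid
#' @export
glomerular_intensity <- function(channel, reference_channel, roi_labels,
                                 roi_names = NULL) {
  if (!identical(dim(channel), dim(reference_channel)) ||
      !identical(dim(channel), dim(roi_labels)))
    abort("channel, reference and label matrices must share dimensions")
  labs <- sort(unique(roi_labels[roi_labels > 0]))
  if (length(labs) == 0) abort("no ROIs in the label matrix")
  out <- purrr::map_dfr(labs, function(lab) {
    sel <- roi_labels == lab
    mc <- mean(channel[sel]); mr <- mean(reference_channel[sel])
    tibble(label = lab, mean_channel = mc, mean_reference = mr,
           normalized = if (mr > 0) mc / mr else NA_real_,
           valid = mr > 0)
  })
  if (any(!out$valid)) warn("ROI(s) with zero reference mean flagged invalid")
  if (!is.null(roi_names))
    out <- dplyr::left_join(out, roi_names, by = "label")
  else out$glomerulus <- sprintf("glom%02d", out$label)
  dplyr::relocate(out, "glomerulus")
}

#' Extract, normalise and average gradient profiles for every channel
#'
#' Convenience wrapper used for opposing-gradient quantification: runs
#' [line_profile()] + [minmax_normalize()] per image and channel, then
#' [average_profiles()] per channel.
#'
#' @param stacks list of [image_stack()] objects (one per antennal lobe)
#' @param start,end,width_px line geometry passed to [line_profile()]
#' @param n_points averaging grid
#' @return tibble with `channel`, `position`, `mean`, `sem`, `n`
#' @export
profile_channels <- function(stacks, start, end, width_px = 10,
                             n_points = 100) {
  chans <- names(stacks[[1]]$channels)
  purrr::map_dfr(chans, function(ch) {
    profs <- lapply(stacks, function(s)
      minmax_normalize(line_profile(s$channels[[ch]], start, end, width_px)))
    dplyr::mutate(average_profiles(profs, n_points), channel = ch,
                  .before = 1)
  })
}
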