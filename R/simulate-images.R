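# Synthetic microscopy fixtures: hard-disk cells of known intensity on a
# known background, with additive Gaussian noise. The simplest model that
# exercises Otsu segmentation, nuclear dilation, and the area/circularity
# gates with exact ground truth.

#' Simulate a three-channel cell-binding image
#'
#' Places non-overlapping disk-shaped cells on a uniform background and
#' renders three channels: `fl` (full-length receptor; bright only over
#' transfected cell bodies), `ecd` (soluble ectodomain binding; a known
#' uniform intensity over every cell footprint) and `nuclear` (DAPI;
#' bright over every nucleus). Control cells carry an `ecd` footprint
#' wide enough to cover their nucleus after the standard ~1.25 um ROI
#' dilation, so noiseless measured means equal the planted intensities
#' exactly.
#'
#' @param n_transfected,n_control cells per class
#' @param image_size `c(rows, cols)` in pixels
#' @param pixel_size_um physical pixel size
#' @param n_z number of (identical) z-planes
#' @param body_radius_um transfected cell body radius
#' @param control_nucleus_radius_um control nucleus radius; recycled over
#'   control cells, so mixes of gate-passing and gate-failing sizes can
#'   be planted
#' @param control_shape `"disk"` or `"bar"` per control cell (recycled);
#'   bars are 3 px wide elongated nuclei that fail the circularity gate
#' @param fl_intensity,nuclear_intensity foreground intensities
#' @param ecd_transfected,ecd_control planted ECD intensities per class
#' @param background background level on every channel
#' @param noise_sd additive Gaussian noise sd (clamped at zero)
#' @param dilation_margin_um extra ECD footprint painted beyond the
#'   control nucleus so the dilated ROI stays inside it
#' @param seed integer seed
#' @param max_tries placement attempts before giving up
#'
#' @return list with `stack` (an [image_stack()] with channels
#'   `fl`, `ecd`, `nuclear`) and `truth` (per-cell tibble: id, class,
#'   centre, radii in px and um, planted channel intensities)
#' @export
gen_cell_image <- function(n_transfected = 5, n_control = 5,
                           image_size = c(256, 256), pixel_size_um = 0.2,
                           n_z = 1,
                           body_radius_um = 2.6,
                           control_nucleus_radius_um = 1.35,
                           control_shape = "disk",
                           fl_intensity = 200, nuclear_intensity = 180,
                           ecd_transfected = 120, ecd_control = 15,
                           background = 10, noise_sd = 0,
                           dilation_margin_um = 1.7, seed = 1,
                           max_tries = 5000) {
  n_cells <- n_transfected + n_control
  cls <- rep(c("transfected", "control"), c(n_transfected, n_control))
  nuc_r_um <- rep_len(control_nucleus_radius_um, max(n_control, 1))
  shp <- rep_len(control_shape, max(n_control, 1))

  px <- function(um) um / pixel_size_um
  # footprint radius: how much room each cell needs on the canvas
  ctrl_idx <- cumsum(cls == "control")
  foot_um <- vapply(seq_len(n_cells), function(i) {
    if (cls[i] == "transfected") return(body_radius_um)
    k <- ctrl_idx[i]
    nuc_r_um[k] * (if (shp[k] == "bar") 6 else 1) + dilation_margin_um
  }, numeric(1))
  foot_px <- ceiling(px(foot_um))

  with_seed(seed, {
    centers <- place_disks(n_cells, image_size, foot_px, max_tries)

    nr <- image_size[1]; nc <- image_size[2]
    fl <- matrix(background, nr, nc)
    ecd <- matrix(background, nr, nc)
    nuc <- matrix(background, nr, nc)

    rows <- list()
    ctrl_i <- 0L
    for (i in seq_len(n_cells)) {
      cy <- centers[i, 1]; cx <- centers[i, 2]
      if (cls[i] == "transfected") {
        body <- disk_pixels(cy, cx, px(body_radius_um), nr, nc)
        nucp <- disk_pixels(cy, cx, px(body_radius_um) * 0.5, nr, nc)
        fl[body] <- fl_intensity
        ecd[body] <- ecd_transfected
        nuc[nucp] <- nuclear_intensity
        rows[[i]] <- tibble(
          cell = i, class = "transfected", cy = cy, cx = cx,
          nucleus_radius_um = body_radius_um * 0.5, shape = "disk",
          fl = fl_intensity, ecd = ecd_transfected, nuclear = nuclear_intensity)
      } else {
        ctrl_i <- ctrl_i + 1L
        r_um <- nuc_r_um[ctrl_i]
        if (shp[ctrl_i] == "bar") {
          nucp <- bar_pixels(cy, cx, half_len = round(px(r_um) * 6),
                             half_wid = 1, nr = nr, nc = nc)
          foot <- bar_pixels(cy, cx, half_len = round(px(r_um) * 6) + ceiling(px(dilation_margin_um)),
                             half_wid = 1 + ceiling(px(dilation_margin_um)), nr = nr, nc = nc)
        } else {
          nucp <- disk_pixels(cy, cx, px(r_um), nr, nc)
          foot <- disk_pixels(cy, cx, px(r_um + dilation_margin_um), nr, nc)
        }
        ecd[foot] <- ecd_control
        nuc[nucp] <- nuclear_intensity
        rows[[i]] <- tibble(
          cell = i, class = "control", cy = cy, cx = cx,
          nucleus_radius_um = r_um, shape = shp[ctrl_i],
          fl = background, ecd = ecd_control, nuclear = nuclear_intensity)
      }
    }

    chans <- list(fl = fl, ecd = ecd, nuclear = nuc)
    if (noise_sd > 0)
      chans <- lapply(chans, function(ch)
        pmax(ch + matrix(rnorm(length(ch), 0, noise_sd), nrow(ch)), 0))
    if (n_z > 1)
      chans <- lapply(chans, function(ch) array(rep(ch, n_z), c(dim(ch), n_z)))

    list(stack = image_stack(chans, pixel_size_um),
         truth = dplyr::bind_rows(rows))
  })
}

# Rejection-sample non-overlapping centres; radius vector in px.
place_disks <- function(n, image_size, radius_px, max_tries) {
  centers <- matrix(0, n, 2)
  placed <- 0L
  for (try in seq_len(max_tries)) {
    r <- radius_px[placed + 1L] + 2
    cy <- runif(1, r + 1, image_size[1] - r)
    cx <- runif(1, r + 1, image_size[2] - r)
    ok <- TRUE
    if (placed > 0) {
      d <- sqrt((centers[seq_len(placed), 1] - cy)^2 +
                (centers[seq_len(placed), 2] - cx)^2)
      ok <- all(d > radius_px[seq_len(placed)] + r + 3)
    }
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- c(round(cy), round(cx))
      if (placed == n) return(centers)
    }
  }
  abort(sprintf("could not place %d non-overlapping cells in %d tries; enlarge the image",
                n, max_tries))
}

# Linear indices of a rasterised disk (centre cy,cx; radius in px).
disk_pixels <- function(cy, cx, r_px, nr, nc) {
  y0 <- max(1, floor(cy - r_px)); y1 <- min(nr, ceiling(cy + r_px))
  x0 <- max(1, floor(cx - r_px)); x1 <- min(nc, ceiling(cx + r_px))
  yy <- rep(y0:y1, times = x1 - x0 + 1)
  xx <- rep(x0:x1, each = y1 - y0 + 1)
  sel <- (yy - cy)^2 + (xx - cx)^2 <= r_px^2
  (xx[sel] - 1L) * nr + yy[sel]
}

bar_pixels <- function(cy, cx, half_len, half_wid, nr, nc) {
  yy <- max(1, cy - half_wid):min(nr, cy + half_wid)
  xx <- max(1, cx - half_len):min(nc, cx + half_len)
  as.vector(outer(yy, (xx - 1L) * nr, `+`))
}

#' Simulate a two-channel opposing-gradient image
#'
#' Emulates the inverse dorsomedial-ventrolateral protein gradients used
#' for line-profile quantification: channel one increases linearly along
#' the chosen axis, channel two decreases.
#'
#' @param image_size `c(rows, cols)`
#' @param axis `"x"` (along columns) or `"y"` (along rows)
#' @param slopes length-2 numeric; intensity change per pixel for the two
#'   channels (second defaults to the negative of the first)
#' @param base intensity at the axis origin for each channel
#' @param channel_names names for the two channels
#' @param noise_sd additive Gaussian noise sd
#' @param pixel_size_um physical pixel size
#' @param seed integer seed
#' @return an [image_stack()] with two channels
#' @export
gen_gradient_image <- function(image_size = c(120, 160), axis = c("x", "y"),
                               slopes = c(1, -1), base = NULL,
                               channel_names = c("tenm", "caps"),
                               noise_sd = 0, pixel_size_um = 0.5, seed = 1) {
  axis <- match.arg(axis)
  L <- if (axis == "x") image_size[2] else image_size[1]
  if (is.null(base))
    base <- ifelse(slopes >= 0, 5, 5 + abs(slopes) * (L - 1))
  coord <- if (axis == "x")
    matrix(rep(0:(image_size[2] - 1), each = image_size[1]), image_size[1])
  else
    matrix(rep(0:(image_size[1] - 1), times = image_size[2]), image_size[1])
  with_seed(seed, {
    chans <- lapply(1:2, function(k) {
      ch <- base[k] + slopes[k] * coord
      if (noise_sd > 0) ch <- ch + matrix(rnorm(length(ch), 0, noise_sd), nrow(ch))
      pmax(ch, 0)
    })
    names(chans) <- channel_names
    image_stack(chans, pixel_size_um)
  })
}
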