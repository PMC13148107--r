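# Automated binding quantification, mirroring the original ImageJ macro:
# max-project, Otsu-segment transfected (receptor-positive) cells on the
# FL channel, identify untransfected controls on the nuclear channel
# minus the FL mask, dilate nuclear ROIs ~1.25 um to approximate cell
# bodies, gate controls by area (7.8-23.4 um^2) and circularity (>0.9),
# and measure mean ECD intensity per ROI.

roi_shape_row <- function(submask, label, pixel_size_um) {
  tibble(label = label,
         pixel_count = sum(submask),
         area_um2 = sum(submask) * pixel_size_um^2,
         circularity = mask_circularity(submask))
}

# crop a label's bounding box with `pad` background pixels around it
crop_label <- function(labels, lab, pad = 0) {
  idx <- which(labels == lab, arr.ind = TRUE)
  r0 <- max(1, min(idx[, 1]) - pad); r1 <- min(nrow(labels), max(idx[, 1]) + pad)
  c0 <- max(1, min(idx[, 2]) - pad); c1 <- min(ncol(labels), max(idx[, 2]) + pad)
  list(rows = r0:r1, cols = c0:c1,
       mask = labels[r0:r1, c0:c1, drop = FALSE] == lab)
}

#' Segment transfected (receptor-positive) cells
#'
#' Otsu threshold on the full-length receptor channel, 8-connected
#' labelling, one ROI per component. Touching cells merge into one ROI;
#' that is a property of connectivity, not an error. The area and
#' circularity gates are optionally applied (`gate = TRUE`), by default
#' they are not.
#'
#' @param fl_channel 2-D receptor-channel matrix
#' @param pixel_size_um physical pixel size
#' @param n_bins Otsu histogram bins
#' @param gate apply the control-cell area/circularity gates here too
#' @param area_range_um2,min_circ gate parameters (used when `gate`)
#' @return list with `rois` (tibble: label, class, pixel_count,
#'   area_um2, circularity), `labels` (label matrix) and `mask`
#' @export
segment_transfected <- function(fl_channel, pixel_size_um, n_bins = 256,
                                gate = FALSE, area_range_um2 = c(7.8, 23.4),
                                min_circ = 0.9) {
  thr <- otsu_threshold(fl_channel, n_bins)
  mask <- fl_channel > thr
  labels <- label_components(mask)
  n <- max(labels)
  if (n == 0) {
    warn("no transfected cells found (empty Otsu mask)")
    return(list(rois = tibble(label = integer(0), roi_class = character(0),
                              pixel_count = integer(0), area_um2 = numeric(0),
                              circularity = numeric(0)),
                labels = labels, mask = mask))
  }
  rois <- purrr::map_dfr(seq_len(n), function(lab) {
    cr <- crop_label(labels, lab, pad = 1)
    roi_shape_row(cr$mask, lab, pixel_size_um)
  })
  rois <- dplyr::mutate(rois, roi_class = "transfected", .after = "label")
  if (gate) {
    keep <- rois$area_um2 >= area_range_um2[1] &
      rois$area_um2 <= area_range_um2[2] & rois$circularity > min_circ
    labels[!(labels %in% rois$label[keep])] <- 0L
    rois <- rois[keep, ]
  }
  list(rois = rois, labels = labels, mask = mask)
}

#' Segment untransfected control cells
#'
#' Otsu threshold on the nuclear channel, subtract the FL-positive mask,
#' label 8-connected nuclei, dilate each by `round(dilation_um /
#' pixel_size_um)` px (disk element) to approximate the cell body, drop
#' ROIs whose dilated footprint overlaps the FL mask, then keep ROIs
#' with dilated area inside `area_range_um2` and circularity above
#' `min_circ`.
#'
#' @param nuclear_channel 2-D nuclear (DAPI) matrix
#' @param fl_mask logical FL-positive mask from [segment_transfected()]
#' @param pixel_size_um physical pixel size
#' @param dilation_um nuclear dilation radius in micrometres
#' @param area_range_um2 inclusive area gate, um^2
#' @param min_circ strict lower circularity bound
#' @param n_bins Otsu histogram bins
#' @return list with `rois` (gated control ROIs, dilated geometry),
#'   `labels` (label matrix of the dilated surviving ROIs) and
#'   `candidates` (pre-gate ROI table with rejection reasons)
#' @export
segment_controls <- function(nuclear_channel, fl_mask, pixel_size_um,
                             dilation_um = 1.25,
                             area_range_um2 = c(7.8, 23.4), min_circ = 0.9,
                             n_bins = 256) {
  thr <- otsu_threshold(nuclear_channel, n_bins)
  nuc_mask <- nuclear_channel > thr & !fl_mask
  nuc_labels <- label_components(nuc_mask)
  n <- max(nuc_labels)
  r_px <- round(dilation_um / pixel_size_um)
  if (r_px < 1) {
    warn("dilation radius below 1 px; skipping dilation")
    r_px <- 0
  }

  out_labels <- matrix(0L, nrow(nuc_mask), ncol(nuc_mask))
  rows <- list()
  for (lab in seq_len(n)) {
    cr <- crop_label(nuc_labels, lab, pad = r_px + 1)
    dmask <- dilate_disk(cr$mask, r_px)
    overlaps <- any(dmask & fl_mask[cr$rows, cr$cols])
    shape <- roi_shape_row(dmask, lab, pixel_size_um)
    in_gate <- shape$area_um2 >= area_range_um2[1] &
      shape$area_um2 <= area_range_um2[2] & shape$circularity > min_circ
    keep <- !overlaps && in_gate
    rows[[lab]] <- dplyr::mutate(shape, roi_class = "control",
                                 overlaps_fl = overlaps, kept = keep,
                                 .after = "label")
    if (keep) {
      sub <- out_labels[cr$rows, cr$cols]
      sub[dmask & sub == 0L] <- lab
      out_labels[cr$rows, cr$cols] <- sub
    }
  }
  candidates <- dplyr::bind_rows(rows)
  kept_tbl <- if (nrow(candidates)) dplyr::filter(candidates, .data$kept)
              else candidates
  # relabel surviving ROIs consecutively
  if (nrow(kept_tbl)) {
    map <- setNames(seq_len(nrow(kept_tbl)), kept_tbl$label)
    out_labels[out_labels > 0] <- map[as.character(out_labels[out_labels > 0])]
    kept_tbl$label <- as.integer(map[as.character(kept_tbl$label)])
  }
  list(rois = dplyr::select(kept_tbl, -"overlaps_fl", -"kept"),
       labels = out_labels, candidates = candidates)
}

#' Mean intensity per ROI on a measurement channel
#'
#' @param seg segmentation list (with `rois` and `labels`) from
#'   [segment_transfected()] or [segment_controls()]
#' @param channel 2-D matrix to measure (e.g. the ECD channel)
#' @param column name of the added column
#' @return the ROI tibble with a per-ROI arithmetic-mean intensity
#'   column appended
#' @export
measure_roi_intensity <- function(seg, channel, column = "mean_intensity") {
  rois <- seg$rois
  if (nrow(rois) == 0) {
    rois[[column]] <- numeric(0)
    return(rois)
  }
  sums <- tapply(channel[seg$labels > 0], seg$labels[seg$labels > 0], mean)
  rois[[column]] <- as.numeric(sums[as.character(rois$label)])
  rois
}

#' Quantify ECD binding on a three-channel stack
#'
#' Full macro: max-project, segment transfected cells on `fl`, controls
#' on `nuclear` (dilated, gated), measure mean `ecd` intensity in both
#' ROI classes.
#'
#' @param stack an [image_stack()] with channels `fl`, `ecd`, `nuclear`
#'   (names configurable)
#' @param channels named character vector mapping roles `fl`, `ecd`,
#'   `nuclear` to channel names in the stack
#' @param gate_transfected also apply the area/circularity gates to
#'   FL-positive ROIs
#' @inheritParams segment_controls
#' @return tibble of ROI records: label, roi_class, pixel_count,
#'   area_um2, circularity, mean_intensity (ECD)
#' @export
quantify_binding <- function(stack,
                             channels = c(fl = "fl", ecd = "ecd",
                                          nuclear = "nuclear"),
                             dilation_um = 1.25,
                             area_range_um2 = c(7.8, 23.4), min_circ = 0.9,
                             gate_transfected = FALSE, n_bins = 256) {
  stack <- max_project(stack)
  fl <- stack$channels[[channels[["fl"]]]]
  ecd <- stack$channels[[channels[["ecd"]]]]
  nuc <- stack$channels[[channels[["nuclear"]]]]
  tr <- segment_transfected(fl, stack$pixel_size_um, n_bins,
                            gate = gate_transfected,
                            area_range_um2 = area_range_um2,
                            min_circ = min_circ)
  ct <- segment_controls(nuc, tr$mask, stack$pixel_size_um,
                         dilation_um = dilation_um,
                         area_range_um2 = area_range_um2,
                         min_circ = min_circ, n_bins = n_bins)
  dplyr::bind_rows(measure_roi_intensity(tr, ecd),
                   measure_roi_intensity(ct, ecd))
}

#' Per-experiment group means for paired binding comparisons
#'
#' Collapses per-cell intensities to per-experiment, per-group means and
#' pairs the transfected and untransfected populations from the same
#' slide; experiments missing either group are excluded with a warning.
#'
#' @param measurements tibble with columns `experiment`, `group`
#'   (`"transfected"`/`"control"`) and `intensity`
#' @return list with `means` (long tibble: experiment, group,
#'   mean_intensity, n_cells) and `pairs` (wide: one row per experiment)
#' @export
summarize_binding <- function(measurements) {
  need <- c("experiment", "group", "intensity")
  if (!all(need %in% names(measurements)))
    abort("measurements need experiment, group and intensity columns")
  means <- dplyr::summarise(
    dplyr::group_by(measurements, .data$experiment, .data$group),
    mean_intensity = mean(.data$intensity), n_cells = dplyr::n(),
    .groups = "drop")
  wide <- tidyr::pivot_wider(dplyr::select(means, -"n_cells"),
                             names_from = "group",
                             values_from = "mean_intensity")
  incomplete <- !stats::complete.cases(wide)
  if (any(incomplete)) {
    warn(sprintf("excluding %d experiment(s) missing a group",
                 sum(incomplete)))
    wide <- wide[!incomplete, ]
    means <- dplyr::semi_join(means, wide, by = "experiment")
  }
  list(means = means, pairs = wide)
}
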