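# Binding quantification on synthetic images with exact ground truth.

test_that("noiseless images are recovered exactly: counts, gates, intensities", {
  img <- gen_cell_image(n_transfected = 3, n_control = 4, seed = 61)
  rois <- quantify_binding(img$stack)
  tr <- rois[rois$roi_class == "transfected", ]
  ct <- rois[rois$roi_class == "control", ]
  expect_equal(nrow(tr), 3)
  expect_equal(nrow(ct), 4)
  expect_true(all(tr$mean_intensity == 120))   # exact, noiseless
  expect_true(all(ct$mean_intensity == 15))
  expect_true(all(ct$area_um2 >= 7.8 & ct$area_um2 <= 23.4))
  expect_true(all(ct$circularity > 0.9))
})

test_that("controls outside the area or circularity gates are rejected", {
  img <- gen_cell_image(
    n_transfected = 1, n_control = 3,
    control_nucleus_radius_um = c(1.35, 2.6, 1.35),  # middle one too large
    control_shape = c("disk", "disk", "bar"),        # bar fails circularity
    image_size = c(300, 300), seed = 62)
  rois <- quantify_binding(img$stack)
  ct <- rois[rois$roi_class == "control", ]
  expect_equal(nrow(ct), 1)                          # only the round, in-gate nucleus
  seg <- segment_controls(img$stack$channels$nuclear,
                          img$stack$channels$fl >
                            otsu_threshold(img$stack$channels$fl),
                          img$stack$pixel_size_um)
  cand <- seg$candidates
  expect_equal(sum(!cand$kept), 2)
  big <- cand[which.max(cand$area_um2), ]
  expect_gt(big$area_um2, 23.4)
})

test_that("a nucleus whose dilated footprint touches a transfected cell is dropped", {
  # build the geometry by hand: one FL-positive disk and one nucleus
  # whose dilation overlaps it, plus one clearly separated nucleus
  nr <- 200
  fl <- matrix(10, nr, nr); nuc <- matrix(10, nr, nr)
  fl[make_disk(nr, nr, 60, 60, 13)] <- 200
  nuc[make_disk(nr, nr, 60, 78, 7)] <- 180    # ~5 px gap; dilation is 6 px
  nuc[make_disk(nr, nr, 150, 150, 7)] <- 180
  stack <- image_stack(list(fl = fl, ecd = matrix(10, nr, nr), nuclear = nuc),
                       pixel_size_um = 0.2)
  rois <- quantify_binding(stack)
  ct <- rois[rois$roi_class == "control", ]
  expect_equal(nrow(ct), 1)
  seg <- segment_controls(nuc, fl > otsu_threshold(fl), 0.2)
  expect_equal(sum(seg$candidates$overlaps_fl), 1)
})

test_that("touching transfected cells merge into a single ROI", {
  nr <- 120
  fl <- matrix(5, nr, nr)
  fl[make_disk(nr, nr, 60, 50, 12)] <- 200
  fl[make_disk(nr, nr, 60, 72, 12)] <- 200    # overlapping disks
  seg <- segment_transfected(fl, 0.2)
  expect_equal(nrow(seg$rois), 1)
})

test_that("noisy ROI means stay within three standard errors of the truth", {
  noise_sd <- 5
  img <- gen_cell_image(n_transfected = 3, n_control = 3,
                        noise_sd = noise_sd, seed = 63)
  rois <- quantify_binding(img$stack)
  for (k in seq_len(nrow(rois))) {
    truth <- if (rois$roi_class[k] == "transfected") 120 else 15
    se <- noise_sd / sqrt(rois$pixel_count[k])
    # segmentation under noise perturbs ROI boundaries slightly; allow
    # 3 SE plus a half-intensity-unit boundary allowance
    expect_lt(abs(rois$mean_intensity[k] - truth), 3 * se + 0.5)
  }
})

test_that("z-stacks are max-projected before segmentation", {
  img <- gen_cell_image(n_transfected = 2, n_control = 2, n_z = 3, seed = 64)
  expect_equal(length(dim(img$stack$channels$fl)), 3)
  rois <- quantify_binding(img$stack)
  expect_equal(sum(rois$roi_class == "transfected"), 2)
  expect_true(all(rois$mean_intensity[rois$roi_class == "transfected"] == 120))
})

test_that("ground truth lists every planted cell deterministically", {
  a <- gen_cell_image(n_transfected = 5, n_control = 5, seed = 65)
  expect_equal(nrow(a$truth), 10)
  expect_equal(sum(a$truth$class == "transfected"), 5)
  b <- gen_cell_image(n_transfected = 5, n_control = 5, seed = 65)
  expect_identical(a$stack$channels$ecd, b$stack$channels$ecd)
  expect_identical(a$truth, b$truth)
})

test_that("impossible placements raise a generation error", {
  expect_error(gen_cell_image(n_transfected = 80, n_control = 0,
                              image_size = c(64, 64), seed = 66,
                              max_tries = 300),
               "non-overlapping")
})

test_that("per-experiment summaries equal a naive group-by and pair slides", {
  set.seed(67)
  df <- tibble::tibble(
    experiment = rep(c("e1", "e2", "e3"), each = 40),
    group = rep(rep(c("transfected", "control"), each = 20), 3),
    intensity = rnorm(120, rep(c(100, 20), each = 20), 5))
  out <- summarize_binding(df)
  expect_equal(nrow(out$pairs), 3)
  oracle <- oracle_group_means(df$intensity,
                               paste(df$experiment, df$group))
  for (i in seq_len(nrow(out$means))) {
    key <- paste(out$means$experiment[i], out$means$group[i])
    expect_equal(out$means$mean_intensity[i], oracle[[key]])
  }
  # one experiment missing a group is excluded with a warning
  df2 <- df[!(df$experiment == "e3" & df$group == "control"), ]
  expect_warning(out2 <- summarize_binding(df2), "missing a group")
  expect_equal(nrow(out2$pairs), 2)
})

test_that("image stacks survive the TIFF + sidecar round trip", {
  img <- gen_cell_image(n_transfected = 2, n_control = 2, seed = 68)
  dir <- tmp_dir()
  path <- file.path(dir, "cells.tif")
  write_image_stack(img$stack, path)
  back <- read_image_stack(path)
  expect_equal(back$pixel_size_um, img$stack$pixel_size_um)
  expect_equal(names(back$channels), names(img$stack$channels))
  # 16-bit quantisation: error bounded by one level of the full scale
  full_scale <- max(vapply(img$stack$channels, max, numeric(1)))
  expect_lt(max(abs(back$channels$ecd - img$stack$channels$ecd)),
            full_scale / 65535 + 1e-9)
  rois <- quantify_binding(back)
  expect_equal(sum(rois$roi_class == "transfected"), 2)
})
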