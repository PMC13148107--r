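#' Multichannel image stack
#'
#' Named channels (2-D matrices or 3-D y/x/z arrays) sharing dimensions,
#' plus the physical pixel size. All quantification operates on these.
#'
#' @param channels named list of non-negative numeric matrices or 3-D
#'   arrays (rows = y, columns = x, third dim = z)
#' @param pixel_size_um physical pixel edge length in micrometres
#' @return an `image_stack`
#' @export
image_stack <- function(channels, pixel_size_um) {
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    abort("channels must be a named list")
  dims <- lapply(channels, function(ch) dim(ch)[1:2])
  if (length(unique(dims)) != 1L)
    abort("all channels must share Y x X dimensions")
  if (pixel_size_um <= 0) abort("pixel_size_um must be positive")
  for (ch in channels)
    if (any(!is.finite(ch)) || any(ch < 0))
      abort("channel values must be finite and non-negative")
  structure(list(channels = channels, pixel_size_um = pixel_size_um),
            class = "image_stack")
}

#' @method print image_stack
#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  nz <- if (length(d) == 3) d[3] else 1L
  cat(sprintf("<image_stack> %d x %d px, %d z-plane(s), %.3g um/px\n",
              d[1], d[2], nz, x$pixel_size_um))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Maximum-intensity projection over z
#'
#' Per-pixel maximum across z-planes for every channel; single-plane
#' stacks pass through unchanged.
#'
#' @param stack an [image_stack()]
#' @return an `image_stack` whose channels are all 2-D
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  chans <- lapply(stack$channels, function(ch) {
    if (length(dim(ch)) == 3) apply(ch, c(1, 2), max) else ch
  })
  image_stack(chans, stack$pixel_size_um)
}

#' Write / read an image stack as multi-page TIFF plus sidecar JSON
#'
#' Channels (z-planes flattened in channel-major order) are stored as
#' 16-bit pages scaled by `intensity_scale`; the sidecar records
#' `pixel_size_um`, channel names, z-depth and the scale so reading
#' restores the original values (to 16-bit quantisation).
#'
#' @param stack an [image_stack()]
#' @param tiff_path output TIFF path
#' @param json_path sidecar path; defaults to `tiff_path` with `.json`
#' @param intensity_scale value mapped to the 16-bit maximum
#' @return `tiff_path`, invisibly
#' @export
write_image_stack <- function(stack, tiff_path,
                              json_path = paste0(tiff_path, ".json"),
                              intensity_scale = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  mx <- max(vapply(stack$channels, max, numeric(1)))
  if (is.null(intensity_scale)) intensity_scale <- max(mx, 1)
  if (mx > intensity_scale) abort("intensity_scale below the image maximum")
  pages <- list()
  nz <- NULL
  for (nm in names(stack$channels)) {
    ch <- stack$channels[[nm]]
    if (length(dim(ch)) == 2) ch <- array(ch, c(dim(ch), 1))
    nz <- dim(ch)[3]
    for (z in seq_len(nz)) pages <- c(pages, list(ch[, , z] / intensity_scale))
  }
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16)
  jsonlite::write_json(list(pixel_size_um = stack$pixel_size_um,
                            channels = names(stack$channels),
                            n_z = nz, intensity_scale = intensity_scale),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(tiff_path, json_path = paste0(tiff_path, ".json")) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  nz <- meta$n_z
  chans <- list()
  for (i in seq_along(meta$channels)) {
    planes <- pages[(i - 1) * nz + seq_len(nz)]
    arr <- array(unlist(planes), c(dim(planes[[1]]), nz)) * meta$intensity_scale
    chans[[meta$channels[i]]] <- if (nz == 1) arr[, , 1] else arr
  }
  image_stack(chans, meta$pixel_size_um)
}
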