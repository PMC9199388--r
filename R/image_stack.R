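#' Create a multi-channel image stack
#'
#' Container for confocal image stacks: a 4-D intensity array indexed
#' (channel, z, y, x), a channel-role map and the pixel size.
#'
#' @param data numeric array with dim (channel, z, y, x); finite,
#'   non-negative intensities.
#' @param channel_roles named integer vector mapping roles (a subset of
#'   `"sixteenS"`, `"eighteenS"`, `"nuclei"`) to channel indices.
#' @param pixel_size_um micrometres per pixel (isotropic in x, y), > 0.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(data, channel_roles, pixel_size_um) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop_input("data must be a 4-D array (channel, z, y, x)")
  if (!all(is.finite(data)))
    stop_input("image intensities must be finite")
  if (any(data < 0))
    stop_input("image intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop_input("pixel_size_um must be a positive number")
  roles <- names(channel_roles)
  if (is.null(roles) || !all(roles %in% c("sixteenS", "eighteenS", "nuclei")))
    stop_input("channel_roles must be named with sixteenS/eighteenS/nuclei")
  if (anyDuplicated(roles)) stop_input("duplicate channel role")
  idx <- as.integer(channel_roles)
  if (any(idx < 1L | idx > dim(data)[1L]))
    stop_input("channel index out of range (stack has %d channels)",
               dim(data)[1L])
  structure(list(data = data, channel_roles = setNames(idx, roles),
                 pixel_size_um = pixel_size_um),
            class = "image_stack")
}

#' Maximum-intensity Z projection of one channel
#'
#' Collapses the 3-D confocal stack of the requested channel to 2-D by
#' taking the per-pixel maximum across z slices.
#'
#' @param stack an [image_stack()].
#' @param role channel role to project (`"sixteenS"`, `"eighteenS"` or
#'   `"nuclei"`).
#' @return numeric matrix (y, x).
#' @export
max_z_projection <- function(stack, role) {
  stopifnot(inherits(stack, "image_stack"))
  if (!role %in% names(stack$channel_roles))
    stop_input("channel role '%s' is not present in the stack", role)
  ch <- stack$channel_roles[[role]]
  d <- dim(stack$data)
  proj <- matrix(stack$data[ch, 1L, , ], d[3L], d[4L])
  if (d[2L] > 1L) {
    for (z in 2:d[2L])
      proj <- pmax(proj, matrix(stack$data[ch, z, , ], d[3L], d[4L]))
  }
  proj
}

#' Min-max normalize an image set
#'
#' Linearly rescales all images of a set together so that the global
#' minimum over the whole set maps to 0 and the global maximum to 1,
#' keeping intensities comparable across images of the set (per-image
#' scaling would destroy cross-condition comparability).  A constant set
#' (min == max) normalizes to all zeros with a warning.
#'
#' @param images list of numeric matrices.
#' @return list of matrices with values in `[0, 1]`.
#' @export
minmax_normalize_set <- function(images) {
  if (!is.list(images) || !length(images))
    stop_input("images must be a non-empty list of matrices")
  vals <- unlist(lapply(images, range), use.names = FALSE)
  if (!all(is.finite(vals))) stop_input("images must be finite")
  lo <- min(vals); hi <- max(vals)
  if (hi == lo) {
    warning("constant image set: normalizing to all zeros")
    return(lapply(images, function(im) array(0, dim(im))))
  }
  lapply(images, function(im) (im - lo) / (hi - lo))
}

#' Read a TIFF file as an image stack
#'
#' Convention: each TIFF page is one z slice; channels are the page's
#' sample dimension when present.  Single-sample (grayscale) multi-page
#' files can instead be read with `pages_are = "channels"` (one page per
#' channel, single z).
#'
#' @param path TIFF file.
#' @param channel_roles named integer vector, see [image_stack()].
#' @param pixel_size_um micrometres per pixel.
#' @param pages_are `"z"` (default) or `"channels"`.
#' @return an [image_stack()].
#' @export
read_image_stack <- function(path, channel_roles, pixel_size_um,
                             pages_are = c("z", "channels")) {
  pages_are <- match.arg(pages_are)
  if (!file.exists(path)) stop_input("file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- dim(pages[[1L]])
  ny <- dims[1L]; nx <- dims[2L]
  nch_page <- if (length(dims) == 3L) dims[3L] else 1L
  if (pages_are == "channels" && nch_page == 1L) {
    arr <- array(0, c(length(pages), 1L, ny, nx))
    for (c_ in seq_along(pages)) arr[c_, 1L, , ] <- pages[[c_]]
  } else {
    arr <- array(0, c(nch_page, length(pages), ny, nx))
    for (z in seq_along(pages)) {
      p <- pages[[z]]
      if (nch_page == 1L) arr[1L, z, , ] <- p
      else for (c_ in seq_len(nch_page)) arr[c_, z, , ] <- p[, , c_]
    }
  }
  image_stack(arr, channel_roles, pixel_size_um)
}

#' Write a binary mask as TIFF
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' Write an image stack as a multi-page TIFF (pages are z slices, channels
#' in the sample dimension), quantized to 16-bit.
#'
#' @param stack an [image_stack()]; intensities must lie in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  if (max(stack$data) > 1)
    stop_input("write_image_stack_tiff expects intensities in [0, 1]")
  pages <- lapply(seq_len(d[2L]), function(z) {
    p <- array(0, c(d[3L], d[4L], d[1L]))
    for (c_ in seq_len(d[1L]))
      p[, , c_] <- round(stack$data[c_, z, , ] * 65535) / 65535
    p
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
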