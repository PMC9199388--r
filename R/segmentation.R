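#' Adaptive-threshold parameters for mycelial masking
#'
#' The mycelial mask is computed per pixel against the local mean intensity
#' in a square window: a pixel is foreground when its intensity exceeds the
#' local mean by more than `offset`.  Components smaller than
#' `min_object_px` (8-connectivity) are removed as speckle.  Defaults suit
#' min-max normalized images in `[0, 1]` with hyphae a few micrometres wide
#' sampled at ~0.1 um/px.
#'
#' @param block_size odd window size in pixels for the local mean.
#' @param offset margin above the local mean (normalized intensity units)
#'   required for foreground.
#' @param min_object_px connected components smaller than this are removed.
#' @return an object of class `adaptive_threshold_params`.
#' @export
adaptive_threshold_params <- function(block_size = 51L, offset = 0.01,
                                      min_object_px = 64L) {
  block_size <- as.integer(block_size)
  if (block_size < 3L || block_size %% 2L == 0L)
    stop_input("block_size must be odd and >= 3")
  if (min_object_px < 0L) stop_input("min_object_px must be >= 0")
  structure(list(block_size = block_size, offset = offset,
                 min_object_px = as.integer(min_object_px)),
            class = "adaptive_threshold_params")
}

# reflection padding of a matrix by r pixels on every side (half-sample
# symmetric: row 0 maps to row 1, row -1 to row 2, ...)
reflect_pad <- function(m, r) {
  n <- nrow(m); p <- ncol(m)
  ri <- reflect_index(seq(1L - r, n + r), n)
  ci <- reflect_index(seq(1L - r, p + r), p)
  m[ri, ci, drop = FALSE]
}

reflect_index <- function(i, n) {
  # fold indices into [1, n] by symmetric reflection
  i <- i - 1L                       # 0-based
  period <- 2L * n
  i <- i %% period
  i <- ifelse(i < 0L, i + period, i)
  i <- ifelse(i >= n, period - 1L - i, i)
  i + 1L
}

# exact box mean via integral image of the reflection-padded input
local_mean <- function(img, block_size) {
  r <- (block_size - 1L) %/% 2L
  pad <- reflect_pad(img, r)
  cs <- apply(pad, 2L, cumsum)
  cs <- t(apply(cs, 1L, cumsum))
  z <- matrix(0, nrow(pad) + 1L, ncol(pad) + 1L)
  z[-1L, -1L] <- cs
  n <- nrow(img); p <- ncol(img); b <- block_size
  iy <- seq_len(n); ix <- seq_len(p)
  s <- z[iy + b, ix + b, drop = FALSE] - z[iy, ix + b, drop = FALSE] -
    z[iy + b, ix, drop = FALSE] + z[iy, ix, drop = FALSE]
  s / (b * b)
}

#' Segment fungal mycelium by adaptive thresholding
#'
#' Generates a mask of the mycelial boundaries from the (projected,
#' normalized) 18S channel: foreground where intensity exceeds the local
#' block mean plus `offset`, with small components removed.  Images smaller
#' than the block are handled by reflection padding inside the local-mean
#' computation.
#'
#' @param img18s numeric matrix (y, x), typically min-max normalized.
#' @param params an [adaptive_threshold_params()].
#' @param pixel_size_um micrometres per pixel, > 0.
#' @return an object of class `mycelial_mask`: list with `mask` (logical
#'   matrix), `area_um2` (`sum(mask) * pixel_size_um^2`) and `params`.
#' @export
mycelial_mask <- function(img18s, params = adaptive_threshold_params(),
                          pixel_size_um) {
  if (!is.matrix(img18s) || !is.numeric(img18s))
    stop_input("img18s must be a numeric matrix")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop_input("pixel_size_um must be a positive number")
  stopifnot(inherits(params, "adaptive_threshold_params"))
  mu <- local_mean(img18s, params$block_size)
  fg <- img18s > mu + params$offset
  if (params$min_object_px > 0L && any(fg)) {
    lab <- cpp_label8(fg)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= params$min_object_px)
    fg <- matrix(lab %in% keep, nrow(fg), ncol(fg))
  }
  structure(list(mask = fg,
                 area_um2 = sum(fg) * pixel_size_um^2,
                 pixel_size_um = pixel_size_um,
                 params = params),
            class = "mycelial_mask")
}
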