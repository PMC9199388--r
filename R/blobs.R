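#' Gaussian blur with reflection boundary
#'
#' Separable Gaussian convolution implemented as banded convolution
#' matrices (one per axis) with half-sample symmetric reflection at the
#' borders; kernel radius is `ceiling(3 * sigma)`.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels; 0 returns the input.
#' @return blurred matrix, same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma < 0) stop_input("sigma must be >= 0")
  if (sigma == 0) return(img)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w <- w / sum(w)
  conv_mat <- function(n) {
    M <- matrix(0, n, n)
    for (o in seq(-r, r)) {
      j <- reflect_index(seq_len(n) + o, n)
      M[cbind(seq_len(n), j)] <- M[cbind(seq_len(n), j)] + w[o + r + 1L]
    }
    M
  }
  My <- conv_mat(nrow(img))
  Mx <- conv_mat(ncol(img))
  My %*% img %*% t(Mx)
}

#' Difference-of-Gaussian detector parameters
#'
#' Defaults target roughly 0.5-1 um bacterial cells imaged at ~0.1 um/px
#' on min-max normalized images: blob scales (sigma) between 1 and 4 px,
#' 5 geometrically spaced scales, and removal of detections overlapping by
#' more than half their disc area.  The response threshold of 0.2 is about
#' 60 percent of the scale-matched response of a bright spot (peak
#' amplitude ~0.8 on the normalized scale) and comfortably above the DoG
#' noise floor when the spot peak exceeds the noise standard deviation by
#' a factor of 5; dimmer spots require lowering it.
#'
#' @param sigma_min,sigma_max smallest/largest blob scale in pixels.
#' @param n_scales number of geometrically spaced scales (>= 2).
#' @param response_threshold minimum scale-normalized DoG response.
#' @param overlap_fraction two retained blobs may overlap (disc model,
#'   radius `sqrt(2) * sigma`) by at most this fraction of the smaller
#'   disc's area.
#' @return an object of class `dog_params`.
#' @export
dog_params <- function(sigma_min = 1, sigma_max = 4, n_scales = 5L,
                       response_threshold = 0.2, overlap_fraction = 0.5) {
  if (sigma_min <= 0 || sigma_min >= sigma_max)
    stop_input("need 0 < sigma_min < sigma_max")
  n_scales <- as.integer(n_scales)
  if (n_scales < 2L) stop_input("n_scales must be >= 2")
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop_input("overlap_fraction must be in [0, 1]")
  structure(list(sigma_min = sigma_min, sigma_max = sigma_max,
                 n_scales = n_scales,
                 response_threshold = response_threshold,
                 overlap_fraction = overlap_fraction),
            class = "dog_params")
}

dog_sigmas <- function(params) {
  exp(seq(log(params$sigma_min), log(params$sigma_max),
          length.out = params$n_scales))
}

# area of intersection of two discs divided by the area of the smaller disc
disc_overlap_fraction <- function(d, r1, r2) {
  rs <- min(r1, r2); rl <- max(r1, r2)
  if (d >= r1 + r2) return(0)
  if (d <= rl - rs) return(1)
  a1 <- rs^2 * acos(pmin(1, pmax(-1, (d^2 + rs^2 - rl^2) / (2 * d * rs))))
  a2 <- rl^2 * acos(pmin(1, pmax(-1, (d^2 + rl^2 - rs^2) / (2 * d * rl))))
  a3 <- 0.5 * sqrt(max(0, (-d + rs + rl) * (d + rs - rl) *
                          (d - rs + rl) * (d + rs + rl)))
  (a1 + a2 - a3) / (pi * rs^2)
}

#' Detect bacterial spots by difference of Gaussians
#'
#' Builds a scale-normalized difference-of-Gaussian scale space
#' (successive Gaussian blurs at geometrically spaced sigmas; adjacent
#' differences divided by `sigma_ratio - 1`), keeps strict local maxima in
#' (y, x, scale) above the response threshold, and prunes overlapping
#' detections keeping the higher response.  Deterministic.
#'
#' @param img16s numeric matrix (y, x), typically the projected and
#'   normalized 16S channel.
#' @param params a [dog_params()].
#' @param source_image_id provenance string stored with the detections.
#' @return an object of class `blob_set`: list with `blobs` (data.frame
#'   `y`, `x`, `sigma`, `response`; coordinates 0-based), `source_image_id`,
#'   `dog_params` and `image_shape`.
#' @export
dog_blob_detect <- function(img16s, params = dog_params(),
                            source_image_id = "image") {
  if (!is.matrix(img16s) || !is.numeric(img16s))
    stop_input("img16s must be a numeric matrix")
  stopifnot(inherits(params, "dog_params"))
  sig <- dog_sigmas(params)
  ratio <- sig[2L] / sig[1L]
  blurs <- lapply(sig, function(s) gaussian_blur(img16s, s))
  nL <- length(sig) - 1L
  cube <- array(0, c(nrow(img16s), ncol(img16s), nL))
  for (i in seq_len(nL))
    cube[, , i] <- (blurs[[i]] - blurs[[i + 1L]]) / (ratio - 1)
  pk <- cpp_local_max3(cube, params$response_threshold)
  blobs <- data.frame(y = pk[, "y"], x = pk[, "x"],
                      sigma = sig[pk[, "scale_idx"] + 1L],
                      response = pk[, "response"])
  # overlap pruning: greedy by decreasing response; lower-response blobs
  # whose disc overlaps a kept blob's disc by more than the allowed
  # fraction are dropped.  Candidate pairs are limited to centers closer
  # than the sum of the two largest possible radii.
  if (nrow(blobs) > 1L && params$overlap_fraction < 1) {
    blobs <- blobs[order(-blobs$response), , drop = FALSE]
    n <- nrow(blobs)
    alive <- rep(TRUE, n)
    rad <- sqrt(2) * blobs$sigma
    for (i in seq_len(n - 1L)) {
      if (!alive[i]) next
      j <- which(alive & seq_len(n) > i)
      if (!length(j)) break
      d <- sqrt((blobs$y[i] - blobs$y[j])^2 + (blobs$x[i] - blobs$x[j])^2)
      near <- j[d < rad[i] + rad[j]]
      for (jj in near) {
        f <- disc_overlap_fraction(
          sqrt((blobs$y[i] - blobs$y[jj])^2 + (blobs$x[i] - blobs$x[jj])^2),
          rad[i], rad[jj])
        if (f > params$overlap_fraction) alive[jj] <- FALSE
      }
    }
    blobs <- blobs[alive, , drop = FALSE]
  }
  blobs <- blobs[order(blobs$y, blobs$x), , drop = FALSE]
  rownames(blobs) <- NULL
  structure(list(blobs = blobs, source_image_id = source_image_id,
                 dog_params = params, image_shape = dim(img16s)),
            class = "blob_set")
}

#' Keep only blobs whose center lies inside the mycelial mask
#'
#' Membership uses the blob's integer-rounded center pixel.
#'
#' @param blobs a `blob_set` from [dog_blob_detect()].
#' @param mask a `mycelial_mask` from [mycelial_mask()] (same image shape).
#' @return a `blob_set` with only the retained blobs.
#' @export
filter_blobs_by_mask <- function(blobs, mask) {
  stopifnot(inherits(blobs, "blob_set"), inherits(mask, "mycelial_mask"))
  if (!identical(as.integer(blobs$image_shape), as.integer(dim(mask$mask))))
    stop_input("mask shape (%s) does not match blob source image shape (%s)",
               paste(dim(mask$mask), collapse = "x"),
               paste(blobs$image_shape, collapse = "x"))
  b <- blobs$blobs
  if (nrow(b)) {
    iy <- as.integer(round(b$y)) + 1L
    ix <- as.integer(round(b$x)) + 1L
    inb <- iy >= 1L & iy <= nrow(mask$mask) & ix >= 1L & ix <= ncol(mask$mask)
    keep <- inb
    keep[inb] <- mask$mask[cbind(iy[inb], ix[inb])]
    b <- b[keep, , drop = FALSE]
    rownames(b) <- NULL
  }
  out <- blobs
  out$blobs <- b
  out
}

#' Bacterial density per 100 square micrometres
#'
#' Counts the blobs whose centers fall inside the mycelial mask and
#' normalizes by the masked area: `density = count / (area_um2 / 100)`,
#' the unit used for cross-condition comparisons.
#'
#' @param blobs a `blob_set`.
#' @param mask a `mycelial_mask` with positive area.
#' @return an object of class `density_estimate`: list with `count`,
#'   `area_um2` and `density_per_100um2`.
#' @export
density_per_100um2 <- function(blobs, mask) {
  stopifnot(inherits(mask, "mycelial_mask"))
  if (mask$area_um2 <= 0)
    stop_input("density is undefined for a zero-area mycelial mask")
  inside <- filter_blobs_by_mask(blobs, mask)
  count <- nrow(inside$blobs)
  structure(list(count = count, area_um2 = mask$area_um2,
                 density_per_100um2 = count / (mask$area_um2 / 100)),
            class = "density_estimate")
}

#' Count blobs in ordered transect regions
#'
#' Counts detections within each rectangle of an ordered, non-overlapping
#' set of regions of interest (e.g. windows A-E along a hyphal bundle from
#' the inoculation point toward the tips).
#'
#' @param blobs a `blob_set`.
#' @param rois data.frame or matrix with columns `y0`, `y1`, `x0`, `x1`:
#'   half-open rectangles `[y0, y1) x [x0, x1)` in 0-based pixel
#'   coordinates, in transect order.
#' @return integer vector of counts, one per ROI in the given order.
#' @export
transect_counts <- function(blobs, rois) {
  stopifnot(inherits(blobs, "blob_set"))
  rois <- as.data.frame(rois)
  need <- c("y0", "y1", "x0", "x1")
  if (!all(need %in% names(rois)))
    stop_input("rois must have columns y0, y1, x0, x1")
  if (any(rois$y1 <= rois$y0) || any(rois$x1 <= rois$x0))
    stop_input("each ROI must have y1 > y0 and x1 > x0")
  n <- nrow(rois)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (rois$y0[i] < rois$y1[j] && rois$y1[i] > rois$y0[j] &&
            rois$x0[i] < rois$x1[j] && rois$x1[i] > rois$x0[j])
          stop_input("ROIs %d and %d overlap", i, j)
      }
    }
  }
  b <- blobs$blobs
  vapply(seq_len(n), function(i)
    sum(b$y >= rois$y0[i] & b$y < rois$y1[i] &
          b$x >= rois$x0[i] & b$x < rois$x1[i]),
    integer(1))
}

#' Run the full quantification pipeline on one image stack
#'
#' Max-intensity Z projection of the 18S and 16S channels, min-max
#' normalization of the two projections as a set, adaptive-threshold
#' mycelial masking of the 18S image, DoG spot detection on the 16S image,
#' mask filtering and density normalization.
#'
#' @param stack an [image_stack()] with `sixteenS` and `eighteenS` roles.
#' @param mask_params an [adaptive_threshold_params()].
#' @param dog a [dog_params()].
#' @param normalize normalize the two projections to the joint min-max
#'   scale before analysis (default TRUE).
#' @return list with `mask` (`mycelial_mask`), `blobs` (all detections),
#'   `blobs_in_mask`, and `density` (`density_estimate`, or NULL with a
#'   warning when the mask area is zero).
#' @export
quantify_stack <- function(stack, mask_params = adaptive_threshold_params(),
                           dog = dog_params(), normalize = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  for (role in c("sixteenS", "eighteenS"))
    if (!role %in% names(stack$channel_roles))
      stop_input("stack lacks required channel role '%s'", role)
  p18 <- max_z_projection(stack, "eighteenS")
  p16 <- max_z_projection(stack, "sixteenS")
  if (normalize) {
    nrm <- minmax_normalize_set(list(p16, p18))
    p16 <- nrm[[1L]]; p18 <- nrm[[2L]]
  }
  msk <- mycelial_mask(p18, mask_params, stack$pixel_size_um)
  blobs <- dog_blob_detect(p16, dog)
  inside <- filter_blobs_by_mask(blobs, msk)
  dens <- if (msk$area_um2 > 0) density_per_100um2(blobs, msk) else {
    warning("zero mycelial area: density undefined")
    NULL
  }
  list(mask = msk, blobs = blobs, blobs_in_mask = inside, density = dens)
}
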