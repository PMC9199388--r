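#' Specification of a synthetic FISH micrograph fixture
#'
#' Describes a two-channel (plus constant nuclei channel) fluorescence
#' image: tubular hyphae in the 18S channel and isotropic Gaussian
#' bacterial spots in the 16S channel, over a constant autofluorescence
#' floor, an optional linear illumination gradient and Gaussian noise.
#' Defaults emulate ~0.5 um bacteria (sigma 0.2 um) inside hyphae ~3 um
#' wide sampled at 0.1 um/px.
#'
#' @param seed integer seed; identical spec + seed gives identical output.
#' @param shape image size (y, x) in pixels.
#' @param pixel_size_um micrometres per pixel.
#' @param n_hyphae number of tubular hyphae (roughly horizontal random
#'   walks with bounded turning angle).
#' @param tube_width_um hyphal tube width in um.
#' @param n_spots_inside,n_spots_outside bacterial spots placed inside /
#'   outside the hyphae.
#' @param spot_sigma_um Gaussian spot scale in um.
#' @param spot_amplitude spot peak intensity above the background floor.
#' @param noise_sigma Gaussian noise standard deviation.
#' @param background_gradient linear intensity ramp per pixel along x
#'   (autofluorescence gradient).
#' @param background_level constant autofluorescence floor.
#' @param density_profile `"uniform"` or `"linear_decay"` (spot density
#'   decaying along the tube axis, proximal to distal).
#' @return an object of class `image_fixture_spec`.
#' @export
image_fixture_spec <- function(seed, shape = c(256L, 256L),
                               pixel_size_um = 0.1, n_hyphae = 2L,
                               tube_width_um = 3, n_spots_inside = 25L,
                               n_spots_outside = 0L, spot_sigma_um = 0.2,
                               spot_amplitude = 0.8, noise_sigma = 0.05,
                               background_gradient = 0,
                               background_level = 0.1,
                               density_profile = c("uniform", "linear_decay")) {
  density_profile <- match.arg(density_profile)
  if (pixel_size_um <= 0) stop_input("pixel_size_um must be > 0")
  if (any(shape < 32L)) stop_input("shape must be at least 32 px")
  if (noise_sigma < 0 || spot_amplitude <= 0 || spot_sigma_um <= 0 ||
      tube_width_um <= 0)
    stop_input("amplitudes, sigmas and widths must be positive")
  structure(list(seed = as.integer(seed), shape = as.integer(shape),
                 pixel_size_um = pixel_size_um, n_hyphae = as.integer(n_hyphae),
                 tube_width_um = tube_width_um,
                 n_spots_inside = as.integer(n_spots_inside),
                 n_spots_outside = as.integer(n_spots_outside),
                 spot_sigma_um = spot_sigma_um,
                 spot_amplitude = spot_amplitude, noise_sigma = noise_sigma,
                 background_gradient = background_gradient,
                 background_level = background_level,
                 density_profile = density_profile),
            class = "image_fixture_spec")
}

# stamp discs of radius r (px) centred at path points into a logical mask
stamp_discs <- function(mask, ys, xs, r) {
  ny <- nrow(mask); nx <- ncol(mask)
  ri <- ceiling(r)
  off <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  off <- off[off$dy^2 + off$dx^2 <= r^2, , drop = FALSE]
  for (i in seq_along(ys)) {
    yy <- round(ys[i]) + off$dy
    xx <- round(xs[i]) + off$dx
    ok <- yy >= 1L & yy <= ny & xx >= 1L & xx <= nx
    mask[cbind(yy[ok], xx[ok])] <- TRUE
  }
  mask
}

# roughly horizontal random-walk centerline with bounded turning angle
hypha_path <- function(y0, ny, nx) {
  ys <- y0; xs <- 1
  ang <- 0
  y <- y0; x <- 1
  while (x < nx && y > 1 && y < ny) {
    ang <- ang + rnorm(1L, 0, 0.08)
    ang <- max(-0.5, min(0.5, ang))
    x <- x + cos(ang)
    y <- y + sin(ang)
    ys <- c(ys, y); xs <- c(xs, x)
  }
  list(y = ys, x = xs)
}

#' Generate a ground-truthed synthetic FISH micrograph
#'
#' Builds the hyphal tube mask (random-walk centerlines dilated to the
#' tube width), places non-overlapping Gaussian spots inside (and
#' optionally outside) the tubes with centers at least one spot radius
#' inside the tube and at least `3 * spot_sigma` apart, synthesizes the
#' 16S/18S/nuclei channels with the shared noise model, and records the
#' ground truth.  Intensities are floats in `[0, 1]`.
#'
#' @param spec an [image_fixture_spec()].
#' @return list with `stack` (an [image_stack()], channels sixteenS = 1,
#'   eighteenS = 2, nuclei = 3, single z slice) and `truth` (list with
#'   `mask` (logical tube mask), `spots` data.frame (`y`, `x` 0-based,
#'   `inside`), and `roi_counts` for 5 equal-width column ROIs).
#' @export
generate_image <- function(spec) {
  stopifnot(inherits(spec, "image_fixture_spec"))
  ny <- spec$shape[1L]; nx <- spec$shape[2L]
  px <- spec$pixel_size_um
  w_px <- spec$tube_width_um / px
  s_px <- spec$spot_sigma_um / px
  with_seed(spec$seed, {
    tube <- matrix(FALSE, ny, nx)
    interior <- matrix(FALSE, ny, nx)
    expanded <- matrix(FALSE, ny, nx)
    if (spec$n_hyphae > 0L) {
      y0s <- ny * (seq_len(spec$n_hyphae) - 0.5) / spec$n_hyphae +
        runif(spec$n_hyphae, -ny * 0.05, ny * 0.05)
      y0s <- pmin(ny - w_px, pmax(w_px, y0s))
      for (h in seq_len(spec$n_hyphae)) {
        p <- hypha_path(y0s[h], ny, nx)
        tube <- stamp_discs(tube, p$y, p$x, w_px / 2)
        interior <- stamp_discs(interior, p$y, p$x,
                                max(1, w_px / 2 - 2 * s_px))
        expanded <- stamp_discs(expanded, p$y, p$x, w_px / 2 + 3 * s_px)
      }
    }

    place_spots <- function(n, allowed, weights_by_x = FALSE) {
      if (n == 0L)
        return(data.frame(y = numeric(0), x = numeric(0)))
      idx <- which(allowed)
      if (!length(idx))
        stop_input("image fixture generation failed: no room to place spots")
      ycand <- (idx - 1L) %% ny + 1L
      xcand <- (idx - 1L) %/% ny + 1L
      wts <- if (weights_by_x) pmax(0.05, 1 - 0.9 * (xcand / nx)) else NULL
      ys <- numeric(0); xs <- numeric(0)
      for (tries in seq_len(5000L)) {
        if (length(ys) == n) break
        j <- sample.int(length(idx), 1L, prob = wts)
        cy <- ycand[j] + runif(1L, -0.45, 0.45)
        cx <- xcand[j] + runif(1L, -0.45, 0.45)
        if (length(ys) &&
            min((ys - cy)^2 + (xs - cx)^2) < (3 * s_px)^2) next
        ys <- c(ys, cy); xs <- c(xs, cx)
      }
      if (length(ys) < n)
        stop_input(paste("image fixture generation failed: could not place",
                         "%d spots with %.1f px separation"), n, 3 * s_px)
      data.frame(y = ys, x = xs)
    }

    border <- ceiling(4 * s_px)
    in_border <- matrix(FALSE, ny, nx)
    in_border[(border + 1L):(ny - border), (border + 1L):(nx - border)] <- TRUE
    sp_in <- place_spots(spec$n_spots_inside, interior & in_border,
                         weights_by_x = (spec$density_profile == "linear_decay"))
    sp_out <- place_spots(spec$n_spots_outside, !expanded & in_border)

    grad <- matrix(rep(spec$background_gradient * (seq_len(nx) - 1L),
                       each = ny), ny, nx)
    ch18 <- spec$background_level + grad +
      (1 - spec$background_level) * tube
    ch16 <- spec$background_level + grad
    add_spot <- function(img, cy, cx) {
      r <- ceiling(4 * s_px)
      yy <- max(1L, floor(cy - r)):min(ny, ceiling(cy + r))
      xx <- max(1L, floor(cx - r)):min(nx, ceiling(cx + r))
      d2 <- outer((yy - cy)^2, (xx - cx)^2, "+")
      img[yy, xx] <- img[yy, xx] +
        spec$spot_amplitude * exp(-d2 / (2 * s_px^2))
      img
    }
    for (i in seq_len(nrow(sp_in)))
      ch16 <- add_spot(ch16, sp_in$y[i], sp_in$x[i])
    for (i in seq_len(nrow(sp_out)))
      ch16 <- add_spot(ch16, sp_out$y[i], sp_out$x[i])
    if (spec$noise_sigma > 0) {
      ch16 <- ch16 + matrix(rnorm(ny * nx, 0, spec$noise_sigma), ny, nx)
      ch18 <- ch18 + matrix(rnorm(ny * nx, 0, spec$noise_sigma), ny, nx)
    }
    clamp <- function(m) pmin(1, pmax(0, m))
    ch16 <- clamp(ch16); ch18 <- clamp(ch18)
    chnuc <- matrix(spec$background_level, ny, nx)

    arr <- array(0, c(3L, 1L, ny, nx))
    arr[1L, 1L, , ] <- ch16
    arr[2L, 1L, , ] <- ch18
    arr[3L, 1L, , ] <- chnuc
    stack <- image_stack(arr, c(sixteenS = 1L, eighteenS = 2L, nuclei = 3L),
                         spec$pixel_size_um)

    spots <- rbind(
      if (nrow(sp_in)) data.frame(y = sp_in$y - 1, x = sp_in$x - 1,
                                  inside = TRUE) else NULL,
      if (nrow(sp_out)) data.frame(y = sp_out$y - 1, x = sp_out$x - 1,
                                   inside = FALSE) else NULL)
    if (is.null(spots))
      spots <- data.frame(y = numeric(0), x = numeric(0), inside = logical(0))

    # truth self-validation: every inside center lies in the tube mask
    if (nrow(sp_in)) {
      stopifnot(all(tube[cbind(round(sp_in$y), round(sp_in$x))]))
    }
    rois <- default_transect_rois(c(ny, nx), 5L)
    roi_counts <- vapply(seq_len(nrow(rois)), function(i)
      sum(spots$inside & spots$x >= rois$x0[i] & spots$x < rois$x1[i]),
      integer(1))
    list(stack = stack,
         truth = list(mask = tube, spots = spots, rois = rois,
                      roi_counts = roi_counts))
  })
}

#' Equal-width column ROIs spanning an image
#'
#' Splits the image into `n` equal-width vertical bands, ordered left to
#' right — the transect windows used along a roughly horizontal hyphal
#' bundle.
#'
#' @param shape image (y, x) size in pixels.
#' @param n number of ROIs.
#' @return data.frame with columns `y0`, `y1`, `x0`, `x1` (0-based,
#'   half-open).
#' @export
default_transect_rois <- function(shape, n = 5L) {
  edges <- floor(seq(0, shape[2L], length.out = n + 1L))
  data.frame(y0 = 0L, y1 = shape[1L], x0 = edges[-(n + 1L)], x1 = edges[-1L])
}
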