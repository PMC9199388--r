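test_that("DoG detection finds planted Gaussian spots exactly", {
  # blank image: nothing
  expect_equal(nrow(dog_blob_detect(matrix(0, 64, 64))$blobs), 0L)
  # one isotropic spot, amplitude 1, sigma 2 px, no noise
  img <- matrix(0, 64, 64)
  cy <- 31.3; cx <- 40.7
  d2 <- outer(((1:64) - cy)^2, ((1:64) - cx)^2, "+")
  img <- exp(-d2 / (2 * 2^2))
  b <- dog_blob_detect(img)$blobs
  expect_equal(nrow(b), 1L)
  expect_lt(abs(b$y - (cy - 1)), 1)
  expect_lt(abs(b$x - (cx - 1)), 1)
  expect_gte(b$sigma, 2 / 1.5)
  expect_lte(b$sigma, 2 * 1.5)
  # 25 planted non-overlapping spots, no noise
  fx <- generate_image(image_fixture_spec(seed = 4, noise_sigma = 0,
                                          n_spots_inside = 25))
  p16 <- max_z_projection(fx$stack, "sixteenS")
  bs <- dog_blob_detect(p16)
  expect_equal(nrow(bs$blobs), 25L)
  tr <- fx$truth$spots
  expect_equal(match_spots(bs$blobs, tr, tol = 2), 25L)
})

test_that("scale-space maxima agree with a brute-force triple-loop oracle", {
  set.seed(17)
  img <- matrix(runif(64 * 64), 64, 64)
  params <- dog_params(sigma_min = 1, sigma_max = 3, n_scales = 3,
                       response_threshold = 0.001, overlap_fraction = 1)
  got <- dog_blob_detect(img, params)$blobs
  # rebuild the same scale space and scan it with explicit loops
  sig <- exp(seq(log(1), log(3), length.out = 3))
  blurs <- lapply(sig, function(s) gaussian_blur(img, s))
  ratio <- sig[2] / sig[1]
  cube <- array(0, c(64, 64, 2))
  for (i in 1:2) cube[, , i] <- (blurs[[i]] - blurs[[i + 1]]) / (ratio - 1)
  want <- NULL
  for (k in 1:2) for (y in 1:64) for (x in 1:64) {
    v <- cube[y, x, k]
    if (v <= 0.001) next
    ismax <- TRUE
    for (dk in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dk == 0 && dy == 0 && dx == 0) next
      yy <- y + dy; xx <- x + dx; kk <- k + dk
      if (yy < 1 || yy > 64 || xx < 1 || xx > 64 || kk < 1 || kk > 2) next
      if (v <= cube[yy, xx, kk]) ismax <- FALSE
    }
    if (ismax) want <- rbind(want, c(y - 1, x - 1, sig[k], v))
  }
  want <- as.data.frame(want)
  names(want) <- c("y", "x", "sigma", "response")
  want <- want[order(want$y, want$x), ]
  rownames(want) <- NULL
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("mask filtering keeps exactly the blobs whose center is masked", {
  shp <- c(40, 40)
  bs <- make_blob_set(y = c(5.2, 10.6, 30.1), x = c(5.4, 19.2, 35.0), shp)
  all_true <- structure(list(mask = matrix(TRUE, 40, 40), area_um2 = 16,
                             pixel_size_um = 0.1,
                             params = adaptive_threshold_params()),
                        class = "mycelial_mask")
  expect_equal(filter_blobs_by_mask(bs, all_true)$blobs, bs$blobs)
  all_false <- all_true; all_false$mask[] <- FALSE; all_false$area_um2 <- 0
  expect_equal(nrow(filter_blobs_by_mask(bs, all_false)$blobs), 0L)
  half <- all_true; half$mask[, 21:40] <- FALSE
  kept <- filter_blobs_by_mask(bs, half)$blobs
  expect_equal(kept$y, c(5.2, 10.6))   # x = 19.2 rounds into the kept half
  wrong <- all_true; wrong$mask <- matrix(TRUE, 10, 10)
  expect_error(filter_blobs_by_mask(bs, wrong), "shape")
  # fixture: 20 spots inside tube, 5 outside
  fx <- generate_image(image_fixture_spec(seed = 5, n_spots_inside = 20,
                                          n_spots_outside = 5,
                                          noise_sigma = 0))
  q <- quantify_stack(fx$stack)
  expect_equal(nrow(q$blobs$blobs), 25L)
  expect_equal(nrow(q$blobs_in_mask$blobs), 20L)
})

test_that("density normalizes counts to 100 square micrometres", {
  mk <- function(area_px, px) structure(
    list(mask = matrix(TRUE, area_px, 1), area_um2 = area_px * px^2,
         pixel_size_um = px, params = adaptive_threshold_params()),
    class = "mycelial_mask")
  # 10 blobs in an area of exactly 100 um^2 (10000 px at 0.1 um/px)
  m <- structure(list(mask = matrix(TRUE, 100, 100), area_um2 = 100,
                      pixel_size_um = 0.1,
                      params = adaptive_threshold_params()),
                 class = "mycelial_mask")
  bs <- make_blob_set(y = seq(5, 90, length.out = 10), x = rep(50, 10),
                      c(100, 100))
  expect_equal(density_per_100um2(bs, m)$density_per_100um2, 10)
  m2 <- m; m2$mask <- matrix(TRUE, 100, 200); m2$area_um2 <- 200
  bs2 <- make_blob_set(y = seq(5, 90, length.out = 10), x = rep(50, 10),
                       c(100, 200))
  expect_equal(density_per_100um2(bs2, m2)$density_per_100um2, 5)
  m0 <- m; m0$mask[] <- FALSE; m0$area_um2 <- 0
  expect_error(density_per_100um2(bs, m0), "zero-area")
})

test_that("transect counting validates ROIs and partitions the image", {
  shp <- c(50, 100)
  bs <- make_blob_set(y = runif(30, 0, 49), x = runif(30, 0, 99), shp)
  whole <- data.frame(y0 = 0, y1 = 50, x0 = 0, x1 = 100)
  expect_equal(transect_counts(bs, whole), 30L)
  empty_roi <- data.frame(y0 = 0, y1 = 50, x0 = 100, x1 = 120)
  expect_equal(transect_counts(bs, empty_roi), 0L)
  rois <- default_transect_rois(shp, 5)
  expect_equal(sum(transect_counts(bs, rois)), 30L)
  bad <- data.frame(y0 = c(0, 0), y1 = c(50, 50), x0 = c(0, 30), x1 = c(40, 60))
  expect_error(transect_counts(bs, bad), "overlap")
  expect_error(transect_counts(bs, data.frame(y0 = 0, y1 = 0, x0 = 0, x1 = 1)),
               "y1 > y0")
})

test_that("transect counts decay along hyphae with a decaying density profile", {
  neg <- 0L
  for (i in 1:10) {
    fx <- generate_image(image_fixture_spec(seed = 300 + i, n_hyphae = 1,
                                            n_spots_inside = 40,
                                            density_profile = "linear_decay"))
    q <- quantify_stack(fx$stack)
    cnt <- transect_counts(q$blobs_in_mask,
                           default_transect_rois(dim(fx$truth$mask), 5))
    slope <- coef(lm(cnt ~ seq_along(cnt)))[2]
    neg <- neg + (slope < 0)
  }
  expect_gte(neg, 9L)
})
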