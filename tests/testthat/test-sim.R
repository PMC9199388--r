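test_that("sequence fixtures are byte-identical across runs of one seed", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.fasta"); f2 <- file.path(d, "b.fasta")
  fx1 <- generate_sequences(seq_fixture_spec(seed = 3))
  fx2 <- generate_sequences(seq_fixture_spec(seed = 3))
  write_records_fasta(fx1$records, f1)
  write_records_fasta(fx2$records, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(fx1$truth, fx2$truth)
  # a different seed changes the sequences
  fx3 <- generate_sequences(seq_fixture_spec(seed = 4))
  expect_false(identical(fx1$records[[1]]$sequence,
                         fx3$records[[1]]$sequence))
})

test_that("sequence fixture truth self-validates", {
  fx <- seed0_fixture()
  recs <- fx$records
  tgt <- recs[[1]]$sequence
  pl <- fx$truth$planted
  for (i in seq_len(nrow(pl))) {
    # planted k-mer present at the recorded position...
    expect_equal(substr(tgt, pl$position[i] + 1, pl$position[i] + 25),
                 pl$kmer[i])
    # ...exactly once across the whole set, absent from other strands
    hits <- vapply(recs, function(r)
      length(gregexpr(pl$kmer[i], r$sequence, fixed = TRUE)[[1]]) *
        (gregexpr(pl$kmer[i], r$sequence, fixed = TRUE)[[1]][1] > 0),
      numeric(1))
    expect_equal(sum(hits), 1)
    rc_hits <- vapply(recs[-1], function(r) gregexpr(
      pl$kmer[i], reverse_complement(r$sequence), fixed = TRUE)[[1]][1] > 0,
      logical(1))
    expect_false(any(rc_hits))
  }
  # the decoy sits in its contig at the recorded edit distance
  dc <- fx$truth$decoys
  if (nrow(dc)) {
    contig <- recs[[which(vapply(recs, `[[`, character(1), "id") ==
                            dc$contig_id)]]$sequence
    expect_equal(substr(contig, dc$position + 1, dc$position + 18),
                 dc$segment)
    origin <- substr(tgt, dc$origin_position + 8, dc$origin_position + 25)
    expect_equal(levenshtein_distance(origin, dc$segment), dc$distance)
  }
})

test_that("unsatisfiable sequence specs fail with a constraint error", {
  # a 25-nt target has one k-mer; planting two separated sites is impossible
  expect_error(generate_sequences(
    seq_fixture_spec(seed = 1, target_len = 30, n_planted_unique = 2)),
    "plant")
})

test_that("image fixtures are deterministic and self-consistent", {
  sp <- image_fixture_spec(seed = 6, n_spots_inside = 12, n_spots_outside = 3)
  fx1 <- generate_image(sp)
  fx2 <- generate_image(sp)
  expect_identical(fx1$stack$data, fx2$stack$data)
  expect_identical(fx1$truth$spots, fx2$truth$spots)
  tr <- fx1$truth
  # every inside spot center lies in the true tube mask
  ins <- tr$spots[tr$spots$inside, ]
  expect_true(all(tr$mask[cbind(round(ins$y) + 1, round(ins$x) + 1)]))
  out <- tr$spots[!tr$spots$inside, ]
  expect_false(any(tr$mask[cbind(round(out$y) + 1, round(out$x) + 1)]))
  # pairwise separation of spot centers is at least 3 spot sigmas
  all_sp <- tr$spots
  dmat <- as.matrix(dist(all_sp[, c("y", "x")]))
  diag(dmat) <- Inf
  expect_gte(min(dmat), 3 * sp$spot_sigma_um / sp$pixel_size_um)
  expect_true(all(fx1$stack$data >= 0 & fx1$stack$data <= 1))
})

test_that("background noise has the requested standard deviation", {
  sp <- image_fixture_spec(seed = 9, shape = c(256, 256), n_hyphae = 1,
                           n_spots_inside = 5, noise_sigma = 0.05)
  fx <- generate_image(sp)
  ch16 <- matrix(fx$stack$data[1, 1, , ], 256, 256)
  # background = pixels more than 5 px away from the tube (8-neighbour
  # dilation applied five times)
  dil <- fx$truth$mask
  for (i in 1:5) {
    d0 <- dil
    dil[-1, ] <- dil[-1, ] | d0[-256, ]; dil[-256, ] <- dil[-256, ] | d0[-1, ]
    dil[, -1] <- dil[, -1] | dil[, -256]; dil[, -256] <- dil[, -256] | dil[, -1]
  }
  patch <- ch16[!dil]
  expect_gte(length(patch), 100 * 100)
  expect_lt(abs(sd(patch) - sp$noise_sigma) / sp$noise_sigma, 0.1)
})

test_that("an empty field yields a zero-area mask and undefined density", {
  fx <- generate_image(image_fixture_spec(seed = 10, n_hyphae = 0,
                                          n_spots_inside = 0,
                                          noise_sigma = 0))
  expect_equal(sum(fx$truth$mask), 0L)
  # a constant stack warns about both the degenerate normalization and the
  # undefined density
  warns <- testthat::capture_warnings(q <- quantify_stack(fx$stack))
  expect_true(any(grepl("zero mycelial area", warns)))
  expect_null(q$density)
  expect_equal(q$mask$area_um2, 0)
  # spots cannot be placed inside hyphae that do not exist
  expect_error(generate_image(image_fixture_spec(seed = 10, n_hyphae = 0,
                                                 n_spots_inside = 5)),
               "room|place")
})
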