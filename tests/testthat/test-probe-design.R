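test_that("k-mer uniqueness handles repeats and reverse-complement hits", {
  cfg4 <- design_config(k = 4, suffix_len = 4, tm_low = 0, tm_high = 100)
  tgt <- list(sequence_record("t", "AAAACCCC", "target"))
  oth <- list(sequence_record("b", "GGGGTTTT", "background"))
  # revcomp screen on: revcomp("GGGGTTTT") = "AAAACCCC" shadows every 4-mer
  expect_equal(nrow(unique_target_kmers(tgt, oth, cfg4)), 0L)
  # revcomp screen off: all five 4-mers are unique
  cfg4b <- design_config(k = 4, suffix_len = 4, tm_low = 0, tm_high = 100,
                         screen_revcomp_background = FALSE)
  uq <- unique_target_kmers(tgt, oth, cfg4b)
  expect_equal(uq$kmer, c("AAAA", "AAAC", "AACC", "ACCC", "CCCC"))
  # within-target repeats are never unique
  cfg2 <- design_config(k = 2, suffix_len = 2, tm_low = 0, tm_high = 100)
  expect_equal(nrow(unique_target_kmers(
    list(sequence_record("t", "ATATAT", "target")), list(), cfg2)), 0L)
  expect_error(unique_target_kmers(list(), list(), cfg4), "target")
})

test_that("k-mer uniqueness agrees with a quadratic brute-force scan", {
  set.seed(5)
  rs <- function(n, alph = c("A", "C", "G", "T")) paste(
    sample(alph, n, TRUE), collapse = "")
  for (i in 1:10) {
    k <- sample(3:6, 1)
    # small alphabet-rich inputs to force collisions; one N-containing region
    tgt <- list(sequence_record("t1", rs(200, c("A", "C", "G", "T", "N")),
                                "target"),
                sequence_record("t2", rs(150), "target"))
    oth <- list(sequence_record("h", rs(250), "host"),
                sequence_record("b", rs(300), "background"))
    cfg <- design_config(k = k, suffix_len = k, tm_low = 0, tm_high = 200)
    got <- unique_target_kmers(tgt, oth, cfg)
    want <- brute_unique_kmers(tgt, oth, k)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("self-complementary 4-mer rule needs two distinct positions", {
  expect_true(has_self_complementary_4mer("GAATTC"))   # GAAT(0) vs ATTC(2)
  expect_false(has_self_complementary_4mer("AAAAAA"))  # TTTT absent
  # a lone palindromic 4-mer does not fold on itself
  expect_false(has_self_complementary_4mer("ACGTAAAAAA"))
  # both published probes must pass
  expect_false(has_self_complementary_4mer("ACGTCATCCCCGCCTTCCTCCGGTT"))
  expect_false(has_self_complementary_4mer("CCATACTCCCCCCGGAACCCAAAAA"))
})

test_that("G-quadruplex motif detection agrees with a recursive scanner", {
  cases <- c("GGGAGGGTGGGCGGG", "GGAGGAGGAGG",
             "ACGTCATCCCCGCCTTCCTCCGGTT", "CCATACTCCCCCCGGAACCCAAAAA",
             "GGGGGGGGGGGGGGG", "GGGTTTTTTTTGGGAGGGAGGG",
             "GGGAGGGAGGGAGGGAGGG", "GGGAGGGAGGGACCCGGG")
  for (s in cases) expect_identical(has_g_quadruplex(s), scan_gquad(s),
                                    label = s)
  expect_true(has_g_quadruplex("GGGAGGGTGGGCGGG"))
  expect_false(has_g_quadruplex("GGAGGAGGAGG"))
  set.seed(31)
  for (i in 1:60) {
    s <- paste(sample(c("G", "G", "G", "A", "T"), sample(12:30, 1), TRUE),
               collapse = "")
    expect_identical(has_g_quadruplex(s), scan_gquad(s), label = s)
  }
})

test_that("the design pipeline accepts exactly the planted fixture site", {
  fx <- seed0_fixture()
  ps <- seed0_design()
  acc <- accepted_probes(ps)
  expect_equal(nrow(acc), 1L)
  expect_equal(acc$position, fx$truth$planted$position)
  expect_equal(acc$target_kmer, fx$truth$planted$kmer)
  expect_equal(acc$probe_sequence, reverse_complement(acc$target_kmer))
  expect_true(all(nchar(acc$target_kmer) == 25L))
  # stage survivor counts are monotonically non-increasing
  expect_true(all(diff(ps$counts) <= 0))
  # every accepted probe satisfies every filter at its recorded metric
  cfg <- ps$config
  expect_true(all(acc$min_suffix_lev > cfg$lev_min_exclusive))
  expect_true(all(acc$tm_c >= cfg$tm_low & acc$tm_c <= cfg$tm_high))
  expect_true(all(acc$flag_selfcomp & acc$flag_gquad))
})

test_that("a target identical to a background contig yields no probes", {
  s <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  recs <- list(sequence_record("t", s, "target"),
               sequence_record("b", s, "background"))
  ps <- design_probes(recs)
  expect_equal(unname(ps$counts["unique"]), 0L)
  expect_equal(nrow(accepted_probes(ps)), 0L)
})

test_that("design output tables round-trip and mark coordinates 1-based in FASTA", {
  d <- withr::local_tempdir()
  ps <- seed0_design()
  tsv <- file.path(d, "probes.tsv")
  write_probe_tsv(ps, tsv)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(ps$candidates))
  expect_equal(back$min_suffix_lev, ps$candidates$min_suffix_lev)
  expect_equal(sum(back$accepted), 1L)
  fa <- file.path(d, "probes.fasta")
  write_probe_fasta(ps, fa)
  lines <- readLines(fa)
  acc <- accepted_probes(ps)
  expect_match(lines[1], sprintf(":%d-%d ", acc$position + 1,
                                 acc$position + 25))
  expect_equal(lines[2], acc$probe_sequence)
})
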