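#' Specification of a synthetic probe-design fixture
#'
#' Describes an rRNA-like input set for [design_probes()]: one target
#' sequence, one host sequence and background contigs, with
#' `n_planted_unique` probe-compliant 25-mer sites planted in the target
#' and optional decoy copies (mutated suffixes placed in the background)
#' that exercise the edit-distance screen.
#'
#' The scaffold is AT-rich (GC 0.25), as in AT-rich Mortierellaceae
#' genomes, and planted suffixes are GC-rich: the composition contrast
#' guarantees planted sites a large edit-distance margin to every scaffold
#' window while ordinary candidates fail the screen.  Default lengths are
#' desk-scale stand-ins for a 16S (~1.5 kb) / 18S (~1.8 kb) + contig set.
#'
#' @param seed integer seed; identical spec + seed gives byte-identical
#'   output.
#' @param target_len,host_len sequence lengths in nt.
#' @param n_background,background_len background contig count and length.
#' @param n_planted_unique number of planted compliant probe sites.
#' @param mutation_distance edit distance of the planted decoy copy
#'   (0 disables the decoy).
#' @return an object of class `seq_fixture_spec`.
#' @export
seq_fixture_spec <- function(seed, target_len = 500L, host_len = 600L,
                             n_background = 6L, background_len = 1200L,
                             n_planted_unique = 1L, mutation_distance = 3L) {
  spec <- list(seed = as.integer(seed), target_len = as.integer(target_len),
               host_len = as.integer(host_len),
               n_background = as.integer(n_background),
               background_len = as.integer(background_len),
               n_planted_unique = as.integer(n_planted_unique),
               mutation_distance = as.integer(mutation_distance))
  if (any(c(spec$target_len, spec$host_len) < 25L))
    stop_input("target_len and host_len must be >= 25")
  if (spec$n_background < 0L || spec$n_planted_unique < 0L ||
      spec$mutation_distance < 0L)
    stop_input("counts and distances must be >= 0")
  if (spec$n_background > 0L && spec$background_len < 25L)
    stop_input("background_len must be >= 25")
  structure(spec, class = "seq_fixture_spec")
}

rand_chars <- function(n, gc = 0.25) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# draw a candidate planted k-mer: AT-rich head, GC-rich suffix
draw_planted_kmer <- function(k, suffix_len) {
  head <- rand_chars(k - suffix_len, gc = 0.25)
  suf <- sample(c("A", "C", "G", "T"), suffix_len, replace = TRUE,
                prob = c(0.06, 0.44, 0.44, 0.06))
  paste(c(head, suf), collapse = "")
}

#' Generate a ground-truthed synthetic sequence set
#'
#' Builds the scaffold, plants `n_planted_unique` probe-compliant sites by
#' rejection sampling (each planted site is unique across the set, within
#' the melting-temperature window, passes both structural filters on its
#' probe, and has suffix edit distance strictly greater than
#' `lev_min_exclusive` to every non-self window), plants one decoy copy of
#' a non-planted target suffix in the background at exactly
#' `mutation_distance` substitutions, and verifies the construction by
#' running [design_probes()]: the accepted set must be exactly the planted
#' set.  Scaffolds for which a non-planted candidate slips through the
#' screen are deterministically resampled.
#'
#' @param spec a [seq_fixture_spec()].
#' @param config the [design_config()] the fixture must comply with.
#' @return list with `records` (list of [sequence_record()]: target
#'   `target_16S`, host `host_18S`, contigs `contig_1..n`) and `truth`
#'   (list with `planted` and `decoys` data.frames).
#' @export
generate_sequences <- function(spec, config = design_config()) {
  stopifnot(inherits(spec, "seq_fixture_spec"))
  k <- config$k; sl <- config$suffix_len
  with_seed(spec$seed, {
    for (attempt in seq_len(25L)) {
      res <- try_generate_sequences(spec, config, k, sl)
      if (!is.null(res)) return(res)
    }
    stop_input(paste("sequence fixture generation failed: could not build a",
                     "scaffold where only planted sites pass the",
                     "edit-distance screen"))
  })
}

try_generate_sequences <- function(spec, config, k, sl) {
  target <- rand_chars(spec$target_len)
  host <- rand_chars(spec$host_len)
  bgs <- lapply(seq_len(spec$n_background),
                function(i) rand_chars(spec$background_len))

  # planted site positions: evenly spaced, >= k apart, clear of both ends
  np <- spec$n_planted_unique
  planted_pos <- integer(0)
  if (np > 0L) {
    planted_pos <- pmax(1L, pmin(spec$target_len - k - 1L,
      floor((seq_len(np) / (np + 1)) * (spec$target_len - k))))
    if (np > 1L && min(diff(planted_pos)) < 2L * k)
      stop_input("target_len too small to plant %d separated sites", np)
    # delimit each planted locus with single ambiguous bases (assembly-gap
    # Ns): k-mers containing N are excluded from candidacy, so no candidate
    # straddling a planted site and its flank can enter the pipeline, and
    # the planted k-mer itself is the only candidate covering its locus
    for (p in planted_pos) {
      target[p] <- "N"            # base immediately 5' of the site (0-based p-1)
      target[p + k + 1L] <- "N"   # base immediately 3' of the site
    }
  }

  seq_strings <- function() c(paste(target, collapse = ""),
                              paste(host, collapse = ""),
                              vapply(bgs, paste, character(1), collapse = ""))

  planted_kmers <- character(np)
  for (i in seq_len(np)) {
    ok <- FALSE
    for (draw in seq_len(200L)) {
      cand <- draw_planted_kmer(k, sl)
      probe <- reverse_complement(cand)
      tm <- melting_temperature(probe, method = config$tm_method)
      if (tm < config$tm_low || tm > config$tm_high) next
      if (has_self_complementary_4mer(probe)) next
      if (has_g_quadruplex(probe) || has_g_quadruplex(cand)) next
      suffix <- substr(cand, k - sl + 1L, k)
      # candidate is not yet in the scaffold: screen against every window
      d <- cpp_min_lev_windows(suffix, seq_strings(), sl,
                               integer(0), integer(0), integer(0))
      if (d >= 0L && d <= config$lev_min_exclusive) next
      target[(planted_pos[i] + 1L):(planted_pos[i] + k)] <-
        strsplit(cand, "", fixed = TRUE)[[1L]]
      planted_kmers[i] <- cand
      ok <- TRUE
      break
    }
    if (!ok)
      stop_input(paste("sequence fixture generation failed: no compliant",
                       "k-mer found for planted site %d (edit-distance",
                       "constraint)"), i)
  }

  # decoy: copy a non-planted target suffix into a background contig with
  # exactly mutation_distance substitutions, so that site fails the screen
  decoys <- data.frame(contig_id = character(0), position = integer(0),
                       segment = character(0), origin_position = integer(0),
                       distance = integer(0), stringsAsFactors = FALSE)
  if (spec$mutation_distance > 0L && spec$n_background > 0L &&
      spec$mutation_distance <= config$lev_min_exclusive) {
    free <- setdiff(seq(0L, spec$target_len - k),
                    unlist(lapply(planted_pos, function(p)
                      seq(max(0L, p - k), p + k))))
    if (length(free)) {
      q <- free[sample.int(length(free), 1L)]
      orig <- paste(target[(q + k - sl + 1L):(q + k)], collapse = "")
      dec <- NULL
      for (draw in seq_len(100L)) {
        s <- strsplit(orig, "", fixed = TRUE)[[1L]]
        idx <- sample.int(sl, spec$mutation_distance)
        for (p in idx)
          s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
        candseg <- paste(s, collapse = "")
        if (levenshtein_distance(orig, candseg) == spec$mutation_distance) {
          dec <- candseg
          break
        }
      }
      if (!is.null(dec)) {
        bpos <- sample.int(spec$background_len - sl + 1L, 1L) - 1L
        bgs[[1L]][(bpos + 1L):(bpos + sl)] <- strsplit(dec, "", fixed = TRUE)[[1L]]
        decoys <- data.frame(contig_id = "contig_1", position = bpos,
                             segment = dec, origin_position = q,
                             distance = spec$mutation_distance,
                             stringsAsFactors = FALSE)
      }
    }
  }

  records <- c(list(sequence_record("target_16S", paste(target, collapse = ""),
                                    "target"),
                    sequence_record("host_18S", paste(host, collapse = ""),
                                    "host")),
               lapply(seq_along(bgs), function(i)
                 sequence_record(sprintf("contig_%d", i),
                                 paste(bgs[[i]], collapse = ""),
                                 "background")))

  planted <- data.frame(source_id = rep("target_16S", np),
                        position = planted_pos, kmer = planted_kmers,
                        stringsAsFactors = FALSE)

  # construction check: the designed set must be exactly the planted set
  ps <- design_probes(records, config)
  acc <- accepted_probes(ps)
  ok <- nrow(acc) == np &&
    (np == 0L || (setequal(acc$position, planted$position) &&
                    setequal(acc$target_kmer, planted$kmer)))
  if (!ok) return(NULL)
  list(records = records, truth = list(planted = planted, decoys = decoys))
}
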