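#' Levenshtein (edit) distance
#'
#' Minimum number of single-character insertions, deletions and
#' substitutions (unit cost) transforming `a` into `b`.  Thin wrapper around
#' [utils::adist()]; vectorised over `b`.
#'
#' @param a single string.
#' @param b character vector.
#' @return integer vector of distances, one per element of `b`.
#' @examples
#' levenshtein_distance("ACGT", "AGT") # 1
#' @export
levenshtein_distance <- function(a, b) {
  if (!is.character(a) || length(a) != 1L) stop_input("a must be one string")
  if (!is.character(b)) stop_input("b must be a character vector")
  as.integer(drop(adist(a, b)))
}

#' Off-target suffix screen for one probe candidate
#'
#' The edit-distance specificity filter: the final `suffix_len` nucleotides
#' of the candidate k-mer are compared with every `suffix_len`-length window
#' of the given sequences, and the candidate passes when the minimum
#' Levenshtein distance strictly exceeds `lev_min_exclusive`.  "Non-self"
#' windows are all windows that do not overlap an exact occurrence of the
#' candidate k-mer itself (overlapping windows share most of their content
#' with the candidate and would make the screen vacuous).
#'
#' When the screened sequences offer no eligible window at all the screen is
#' vacuous: `min_distance` is reported as `Inf` and the candidate passes.
#'
#' @param candidate_kmer the candidate target k-mer (length `config$k`).
#' @param all_sequences list of [sequence_record()] objects to screen
#'   against.
#' @param config a [design_config()].
#' @return list with `min_distance` (integer or `Inf`) and `pass` (logical).
#' @export
suffix_indel_screen <- function(candidate_kmer, all_sequences, config = design_config()) {
  validate_record_set(all_sequences)
  k <- config$k
  if (nchar(candidate_kmer) != k)
    stop_input("candidate k-mer must have length k = %d", k)
  suffix <- substr(candidate_kmer, k - config$suffix_len + 1L, k)
  seqs <- vapply(all_sequences, `[[`, character(1), "sequence")
  # exclusion intervals: every exact occurrence of the candidate k-mer
  ex_seq <- integer(0); ex_lo <- integer(0); ex_hi <- integer(0)
  for (s in seq_along(seqs)) {
    hits <- gregexpr(candidate_kmer, seqs[s], fixed = TRUE)[[1L]]
    if (hits[1L] > 0L) {
      ex_seq <- c(ex_seq, rep.int(s - 1L, length(hits)))
      ex_lo <- c(ex_lo, as.integer(hits) - 1L)
      ex_hi <- c(ex_hi, as.integer(hits) - 1L + k)
    }
  }
  d <- cpp_min_lev_windows(suffix, seqs, config$suffix_len,
                           ex_seq, ex_lo, ex_hi)
  min_distance <- if (d < 0L) Inf else d
  list(min_distance = min_distance,
       pass = min_distance > config$lev_min_exclusive)
}
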