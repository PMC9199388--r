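#' Probe design configuration
#'
#' Parameters of the probe-design pipeline.  Defaults reflect the design
#' used for 16S/18S rRNA HCR-FISH probes: 25-mer target sites, an 18-nt
#' suffix edit-distance screen requiring distance strictly greater than 6,
#' and structural filters on the assembled probe.  The melting-temperature
#' window is bounded below by the 37 degree hybridization temperature; the
#' upper bound (90) is a permissive cap and both bounds are configurable.
#'
#' @param k probe/target site length in nt.
#' @param suffix_len length of the probe 3'-terminal target segment used in
#'   the edit-distance screen.
#' @param lev_min_exclusive candidates pass when their minimum suffix
#'   Levenshtein distance strictly exceeds this value.
#' @param tm_low,tm_high acceptable melting-temperature window, degrees C.
#' @param tm_method `"wallace"` or `"nearest_neighbor"`, see
#'   [melting_temperature()].
#' @param forbid_selfcomp_4mers reject probes containing a 4-mer and its
#'   reverse complement at two distinct positions.
#' @param forbid_g_quadruplex reject probes matching the canonical
#'   G-quadruplex motif (four runs of >= 3 G, loops of 1-7 nt).
#' @param screen_revcomp_background also require target k-mers to be absent
#'   from the reverse complement of non-target sequences (background contigs
#'   are double-stranded DNA).
#' @param lev_scope `"all"` screens suffix windows of every input sequence;
#'   `"target"` restricts the screen to the target sequences.
#' @return an object of class `design_config`.
#' @export
design_config <- function(k = 25L, suffix_len = 18L, lev_min_exclusive = 6L,
                          tm_low = 37, tm_high = 90,
                          tm_method = c("wallace", "nearest_neighbor"),
                          forbid_selfcomp_4mers = TRUE,
                          forbid_g_quadruplex = TRUE,
                          screen_revcomp_background = TRUE,
                          lev_scope = c("all", "target")) {
  tm_method <- match.arg(tm_method)
  lev_scope <- match.arg(lev_scope)
  k <- as.integer(k); suffix_len <- as.integer(suffix_len)
  lev_min_exclusive <- as.integer(lev_min_exclusive)
  if (k < 1L) stop_input("k must be >= 1")
  if (suffix_len < 1L || suffix_len > k)
    stop_input("suffix_len must satisfy 0 < suffix_len <= k")
  if (tm_low > tm_high) stop_input("tm_low must be <= tm_high")
  if (lev_min_exclusive < 0L) stop_input("lev_min_exclusive must be >= 0")
  structure(list(k = k, suffix_len = suffix_len,
                 lev_min_exclusive = lev_min_exclusive,
                 tm_low = tm_low, tm_high = tm_high, tm_method = tm_method,
                 forbid_selfcomp_4mers = isTRUE(forbid_selfcomp_4mers),
                 forbid_g_quadruplex = isTRUE(forbid_g_quadruplex),
                 screen_revcomp_background = isTRUE(screen_revcomp_background),
                 lev_scope = lev_scope),
            class = "design_config")
}

#' Target k-mers unique across the whole input set
#'
#' Returns the k-mers that occur exactly once within the union of target
#' sequences and never in any other sequence (nor, when
#' `screen_revcomp_background` is set, in the reverse complement of any
#' other sequence).  K-mers containing N are excluded from candidacy.
#'
#' @param targets list of target [sequence_record()]s (non-empty).
#' @param others list of host/background records (possibly empty).
#' @param config a [design_config()].
#' @return data.frame with `source_id`, `position` (0-based) and `kmer`,
#'   ordered by (source_id, position).
#' @export
unique_target_kmers <- function(targets, others, config = design_config()) {
  if (!length(targets)) stop_input("at least one target sequence is required")
  validate_record_set(c(targets, others))
  k <- config$k
  tk <- do.call(rbind, lapply(targets, function(r) {
    km <- enumerate_kmers(r$sequence, k)
    if (nrow(km)) km$source_id <- r$id
    km
  }))
  if (is.null(tk) || !nrow(tk))
    return(data.frame(source_id = character(0), position = integer(0),
                      kmer = character(0), stringsAsFactors = FALSE))
  tk <- tk[!grepl("N", tk$kmer, fixed = TRUE), , drop = FALSE]
  other_kmers <- unlist(lapply(others, function(r) {
    km <- c(enumerate_kmers(r$sequence, k)$kmer)
    if (config$screen_revcomp_background)
      km <- c(km, enumerate_kmers(reverse_complement(r$sequence), k)$kmer)
    km
  }), use.names = FALSE)
  tab <- table(tk$kmer)
  keep <- tab[tk$kmer] == 1L & !(tk$kmer %in% other_kmers)
  out <- tk[keep, c("source_id", "position", "kmer"), drop = FALSE]
  out <- out[order(out$source_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Does a probe contain a self-complementary 4-mer pair?
#'
#' TRUE iff there are two distinct start positions i != j with
#' `probe[i:i+3] == reverse_complement(probe[j:j+3])`.  A single occurrence
#' of a palindromic 4-mer (i == j) does not trigger rejection: such probes
#' cannot fold on that 4-mer alone, and the rule would otherwise reject
#' probes beginning with e.g. ACGT.
#'
#' @param probe nucleotide string, length >= 4.
#' @return logical.
#' @examples
#' has_self_complementary_4mer("GAATTC") # TRUE: GAAT(0) vs ATTC(2)
#' @export
has_self_complementary_4mer <- function(probe) {
  n <- nchar(probe)
  if (n < 4L) stop_input("probe must have length >= 4")
  check_alphabet(probe)
  k4 <- substring(probe, 1:(n - 3L), 4:n)
  rc4 <- vapply(k4, reverse_complement, character(1), USE.NAMES = FALSE)
  for (i in seq_along(k4)) {
    for (j in seq_along(k4)) {
      if (i != j && k4[i] == rc4[j]) return(TRUE)
    }
  }
  FALSE
}

#' Does a probe contain a canonical G-quadruplex motif?
#'
#' The canonical intramolecular quadruplex motif: four runs of at least
#' three consecutive G separated by loops of 1-7 arbitrary nucleotides.
#'
#' @param probe nucleotide string.
#' @return logical.
#' @examples
#' has_g_quadruplex("GGGAGGGTGGGCGGG") # TRUE (minimal motif)
#' @export
has_g_quadruplex <- function(probe) {
  check_alphabet(probe)
  grepl("G{3,}(?:[ACGTN]{1,7}G{3,}){3}", probe, perl = TRUE)
}

#' Design taxon-specific FISH probes
#'
#' Full pipeline: enumerate every k-mer of the target sequence(s)
#' (k-mers containing N excluded), keep those unique across the whole input
#' set, apply the melting-temperature window, apply the suffix
#' edit-distance off-target screen, reverse-complement surviving target
#' sites into probes, and apply the structural filters.  Deterministic:
#' identical input and configuration give identical output.
#'
#' Cheap metrics (melting temperature, probe sequence, structural flags)
#' are computed for every uniqueness-stage candidate; the suffix screen,
#' the expensive stage, is evaluated only for candidates that survive the
#' uniqueness and melting-temperature filters (its flag is NA otherwise —
#' such candidates are already rejected).
#'
#' @param records list of [sequence_record()]s; at least one must have
#'   role `"target"`.
#' @param config a [design_config()].
#' @return an object of class `probe_set`: list with `candidates` (one row
#'   per unique-stage candidate with all metrics and flags plus `accepted`),
#'   `config`, and `counts` of survivors after each sequential stage
#'   (kmerize, unique, tm, levenshtein, structure).
#' @export
design_probes <- function(records, config = design_config()) {
  validate_record_set(records)
  roles <- vapply(records, `[[`, character(1), "role")
  targets <- records[roles == "target"]
  others <- records[roles != "target"]
  if (!length(targets)) stop_input("at least one target record is required")

  k <- config$k
  n_kmerize <- 0L
  for (r in targets) {
    km <- enumerate_kmers(r$sequence, k)$kmer
    n_kmerize <- n_kmerize + sum(!grepl("N", km, fixed = TRUE))
  }

  uq <- unique_target_kmers(targets, others, config)
  n_unique <- nrow(uq)

  cand <- uq
  if (n_unique) {
    cand$target_kmer <- cand$kmer
    cand$kmer <- NULL
    cand$probe_sequence <- vapply(cand$target_kmer, reverse_complement,
                                  character(1), USE.NAMES = FALSE)
    cand$tm_c <- vapply(cand$probe_sequence, melting_temperature, numeric(1),
                        method = config$tm_method, USE.NAMES = FALSE)
    cand$flag_unique <- TRUE
    cand$flag_tm <- cand$tm_c >= config$tm_low & cand$tm_c <= config$tm_high

    # suffix screen on uniqueness+Tm survivors only
    scope_recs <- if (config$lev_scope == "target") targets else records
    seqs <- vapply(scope_recs, `[[`, character(1), "sequence")
    scope_ids <- vapply(scope_recs, `[[`, character(1), "id")
    eval_idx <- which(cand$flag_tm)
    cand$min_suffix_lev <- NA_real_
    cand$flag_lev <- NA
    if (length(eval_idx)) {
      suffixes <- substr(cand$target_kmer[eval_idx],
                         k - config$suffix_len + 1L, k)
      src <- match(cand$source_id[eval_idx], scope_ids) - 1L
      src[is.na(src)] <- -1L
      lo <- cand$position[eval_idx]
      hi <- lo + k
      mins <- cpp_screen_batch(suffixes, src, as.integer(lo), as.integer(hi),
                               seqs, config$suffix_len)
      mins_r <- ifelse(mins < 0L, Inf, as.numeric(mins))
      cand$min_suffix_lev[eval_idx] <- mins_r
      cand$flag_lev[eval_idx] <- mins_r > config$lev_min_exclusive
    }

    cand$flag_selfcomp <- if (config$forbid_selfcomp_4mers)
      !vapply(cand$probe_sequence, has_self_complementary_4mer, logical(1),
              USE.NAMES = FALSE) else TRUE
    cand$flag_gquad <- if (config$forbid_g_quadruplex)
      !vapply(cand$probe_sequence, has_g_quadruplex, logical(1),
              USE.NAMES = FALSE) else TRUE
    cand$accepted <- cand$flag_unique & cand$flag_tm &
      !is.na(cand$flag_lev) & cand$flag_lev &
      cand$flag_selfcomp & cand$flag_gquad
    cand <- cand[order(cand$source_id, cand$position), , drop = FALSE]
    rownames(cand) <- NULL
  } else {
    cand <- data.frame(source_id = character(0), position = integer(0),
                       target_kmer = character(0), probe_sequence = character(0),
                       tm_c = numeric(0), flag_unique = logical(0),
                       flag_tm = logical(0), min_suffix_lev = numeric(0),
                       flag_lev = logical(0), flag_selfcomp = logical(0),
                       flag_gquad = logical(0), accepted = logical(0),
                       stringsAsFactors = FALSE)
  }

  n_tm <- sum(cand$flag_unique & cand$flag_tm)
  n_lev <- sum(cand$flag_unique & cand$flag_tm &
                 !is.na(cand$flag_lev) & cand$flag_lev)
  n_struct <- sum(cand$accepted)
  counts <- c(kmerize = n_kmerize, unique = n_unique, tm = n_tm,
              levenshtein = n_lev, structure = n_struct)
  structure(list(candidates = cand, config = config, counts = counts),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat("FISH probe set (k =", x$config$k, ")\n")
  cat("stage survivors:",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  acc <- accepted_probes(x)
  if (nrow(acc)) {
    cat("accepted probes:\n")
    print(acc[, c("source_id", "position", "probe_sequence", "tm_c",
                  "min_suffix_lev")], ...)
  } else cat("no probes accepted\n")
  invisible(x)
}

#' Accepted probes of a probe set
#' @param ps a `probe_set` from [design_probes()].
#' @return data.frame of the accepted candidate rows.
#' @export
accepted_probes <- function(ps) {
  stopifnot(inherits(ps, "probe_set"))
  ps$candidates[ps$candidates$accepted, , drop = FALSE]
}

#' Write the probe candidate table as TSV
#'
#' Columns: id, source_id, position (0-based target-site start), strand
#' ("-": the probe is the reverse complement of the target site),
#' target_kmer, probe_sequence, tm_c, min_suffix_lev, the flag_* columns
#' and accepted.
#'
#' @param ps a `probe_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_tsv <- function(ps, path) {
  stopifnot(inherits(ps, "probe_set"))
  d <- ps$candidates
  out <- data.frame(id = if (nrow(d)) sprintf("%s_%d", d$source_id, d$position + 1L)
                         else character(0),
                    source_id = d$source_id, position = d$position,
                    strand = rep("-", nrow(d)), target_kmer = d$target_kmer,
                    probe_sequence = d$probe_sequence, tm_c = d$tm_c,
                    min_suffix_lev = d$min_suffix_lev,
                    flag_unique = d$flag_unique, flag_tm = d$flag_tm,
                    flag_lev = d$flag_lev, flag_selfcomp = d$flag_selfcomp,
                    flag_gquad = d$flag_gquad, accepted = d$accepted,
                    stringsAsFactors = FALSE)
  write_atomic(out, path, sep = "\t")
  invisible(path)
}

#' Write accepted probes as FASTA
#'
#' Headers record the target site as `source_id:start-end` in 1-based
#' inclusive coordinates for human readability (the candidate table keeps
#' 0-based half-open coordinates).
#'
#' @param ps a `probe_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_fasta <- function(ps, path) {
  acc <- accepted_probes(ps)
  lines <- character(0)
  if (nrow(acc)) {
    headers <- sprintf(">%s:%d-%d probe", acc$source_id, acc$position + 1L,
                       acc$position + nchar(acc$target_kmer))
    lines <- as.vector(rbind(headers, acc$probe_sequence))
  }
  tmp <- paste0(path, ".tmp")
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

# atomic table writer: write to temp file in the same directory, then rename
write_atomic <- function(df, path, sep = ",") {
  tmp <- paste0(path, ".tmp")
  write.table(df, tmp, sep = sep, quote = FALSE, row.names = FALSE, na = "NA")
  file.rename(tmp, path)
  invisible(path)
}
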