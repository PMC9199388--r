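#' Create a sequence record
#'
#' A nucleotide sequence plus the role it plays in probe design.  Sequences
#' are upper-cased and U is mapped to T at ingestion so RNA and DNA inputs
#' behave identically; the alphabet is restricted to A, C, G, T, N.
#'
#' @param id character identifier, unique within an input set.
#' @param sequence nucleotide string (A/C/G/T/N; U accepted, mapped to T).
#' @param role one of `"target"`, `"host"`, `"background"`.
#' @return an object of class `sequence_record` with fields `id`, `sequence`
#'   and `role`.
#' @examples
#' sequence_record("16S", "acguacgu", "target")$sequence
#' @export
sequence_record <- function(id, sequence, role = c("target", "host", "background")) {
  role <- match.arg(role)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop_input("record id must be a non-empty string")
  if (!is.character(sequence) || length(sequence) != 1L)
    stop_input("sequence must be a single string")
  seq <- chartr("u", "t", sequence)
  seq <- toupper(chartr("U", "T", seq))
  check_alphabet(seq, id)
  if (!nzchar(seq)) stop_input("record '%s': sequence is empty", id)
  structure(list(id = id, sequence = seq, role = role),
            class = "sequence_record")
}

check_alphabet <- function(seq, id = "sequence") {
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L)
    stop_input("record '%s': invalid nucleotide '%s' at position %d",
               id, substr(seq, bad, bad), bad)
  invisible(seq)
}

validate_record_set <- function(records) {
  if (!length(records)) stop_input("no sequence records given")
  ok <- vapply(records, inherits, logical(1), "sequence_record")
  if (!all(ok)) stop_input("all elements must be sequence_record objects")
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop_input("duplicate record id '%s'", ids[duplicated(ids)][1L])
  invisible(records)
}

#' Read sequence records from a FASTA file
#'
#' Validates the file line-by-line (reporting the first offending line
#' number) and parses it with [Biostrings::readDNAStringSet()].
#'
#' @param path FASTA file path.
#' @param role role assigned to every record in the file.
#' @return list of [sequence_record()] objects.
#' @export
read_sequence_records <- function(path, role = c("target", "host", "background")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop_input("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  in_seq <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) { in_seq <- TRUE; next }
    if (!in_seq)
      stop_input("malformed FASTA %s: line %d precedes any '>' header", path, i)
    if (grepl("[^ACGTUNacgtun]", ln))
      stop_input("malformed FASTA %s: invalid character on line %d", path, i)
  }
  ss <- Biostrings::readBStringSet(path)  # U handled by sequence_record
  if (!length(ss)) stop_input("FASTA %s contains no records", path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  recs <- lapply(seq_along(ss), function(i)
    sequence_record(ids[i], as.character(ss[[i]]), role))
  validate_record_set(recs)
  recs
}

#' Reverse complement of a nucleotide sequence
#'
#' Probe assembly takes the reverse complement of each unique target site;
#' N maps to N.  The operation is an involution: applying it twice returns
#' the input.
#'
#' @param seq nucleotide string over A/C/G/T/N.
#' @return the reverse complement, same length as the input.
#' @examples
#' reverse_complement("ACGT") # palindrome
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L)
    stop_input("seq must be a single string")
  if (!nzchar(seq)) stop_input("cannot reverse-complement an empty sequence")
  check_alphabet(seq)
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Enumerate every k-mer of a sequence
#'
#' @param seq nucleotide string.
#' @param k window length (>= 1).
#' @return data.frame with `position` (0-based start) and `kmer`; empty when
#'   `k > nchar(seq)`.
#' @export
enumerate_kmers <- function(seq, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop_input("k must be a positive integer, got %s", format(k))
  k <- as.integer(k)
  n <- nchar(seq)
  if (k > n)
    return(data.frame(position = integer(0), kmer = character(0),
                      stringsAsFactors = FALSE))
  starts <- seq_len(n - k + 1L)
  data.frame(position = starts - 1L,
             kmer = substring(seq, starts, starts + k - 1L),
             stringsAsFactors = FALSE)
}

# SantaLucia & Hicks (2004) unified nearest-neighbour parameters.
# dH kcal/mol, dS cal/(mol K); keys are the 5'->3' dinucleotide on one strand.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
            GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
            TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
            GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            CC = -19.9)

#' Melting temperature of an oligonucleotide
#'
#' `wallace` is the Wallace rule 2(A+T) + 4(G+C), exact and fast, the
#' default for screening.  `nearest_neighbor` is the SantaLucia & Hicks
#' (2004) unified nearest-neighbour model with terminal A.T/G.C initiation
#' penalties, monovalent-salt entropy correction
#' dS += 0.368 (N-1) ln([Na+]) and duplex concentration term
#' Tm = 1000 dH / (dS + R ln(c)) with R = 1.987 cal/(mol K); defaults are
#' 25 nM probe and template ([Na+] = 50 mM), i.e. c = 12.5 nM.
#'
#' @param seq nucleotide string, length >= 2, no N.
#' @param method `"wallace"` or `"nearest_neighbor"`.
#' @param dnac1,dnac2 strand concentrations in nM (NN method only).
#' @param Na monovalent cation concentration in mM (NN method only).
#' @return temperature in degrees Celsius.
#' @examples
#' melting_temperature("ACGT") # 12
#' @export
melting_temperature <- function(seq, method = c("wallace", "nearest_neighbor"),
                                dnac1 = 25, dnac2 = 25, Na = 50) {
  method <- match.arg(method)
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) < 2L)
    stop_input("seq must be a single string of length >= 2")
  check_alphabet(seq)
  if (grepl("N", seq, fixed = TRUE))
    stop_input("melting temperature is undefined for sequences containing N")
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (method == "wallace") {
    at <- sum(s %in% c("A", "T"))
    gc <- sum(s %in% c("G", "C"))
    return(2 * at + 4 * gc)
  }
  steps <- paste0(s[-length(s)], s[-1L])
  H <- sum(.NN_DH[steps])
  S <- sum(.NN_DS[steps])
  for (term in c(s[1L], s[length(s)])) {
    if (term %in% c("A", "T")) { H <- H + 2.3; S <- S + 4.1 }
    else                        { H <- H + 0.1; S <- S - 2.8 }
  }
  S <- S + 0.368 * (length(s) - 1L) * log(Na * 1e-3)
  conc <- (dnac1 - dnac2 / 2) * 1e-9
  1000 * H / (S + 1.987 * log(conc)) - 273.15
}

#' Write sequence records to FASTA
#'
#' @param records list of [sequence_record()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records_fasta <- function(records, path) {
  validate_record_set(records)
  ss <- Biostrings::DNAStringSet(vapply(records, `[[`, character(1), "sequence"))
  names(ss) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(ss, filepath = path, width = 70L)
  invisible(path)
}
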