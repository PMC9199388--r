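# Independent oracles and shared fixtures for the test suite.

# naive exponential-recursion edit distance (independent of adist / Rcpp)
naive_lev <- function(a, b) {
  if (!nchar(a)) return(nchar(b))
  if (!nchar(b)) return(nchar(a))
  ta <- substr(a, 2L, nchar(a)); tb <- substr(b, 2L, nchar(b))
  cost <- as.integer(substr(a, 1L, 1L) != substr(b, 1L, 1L))
  min(naive_lev(ta, b) + 1L, naive_lev(a, tb) + 1L, naive_lev(ta, tb) + cost)
}

# quadratic brute-force unique-k-mer scan over explicit window lists
brute_unique_kmers <- function(targets, others, k, screen_rc = TRUE) {
  wins <- function(s) if (nchar(s) >= k)
    substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)) else character(0)
  rc <- function(s) endofish::reverse_complement(s)
  tk <- lapply(targets, function(r) wins(r$sequence))
  all_t <- unlist(tk)
  other_w <- unlist(lapply(others, function(r)
    c(wins(r$sequence), if (screen_rc) wins(rc(r$sequence)))))
  out <- NULL
  for (i in seq_along(targets)) {
    for (p in seq_along(tk[[i]])) {
      km <- tk[[i]][p]
      if (grepl("N", km, fixed = TRUE)) next
      if (sum(all_t == km) == 1L && !any(other_w == km))
        out <- rbind(out, data.frame(source_id = targets[[i]]$id,
                                     position = p - 1L, kmer = km,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(source_id = character(0), position = integer(0),
                      kmer = character(0), stringsAsFactors = FALSE)
  out[order(out$source_id, out$position), , drop = FALSE]
}

# recursive G-quadruplex scanner (regex-free): can the string be parsed,
# starting at any position, as four runs of >= 3 G separated by loops of
# 1-7 arbitrary nucleotides?
scan_gquad <- function(s) {
  n <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  run_from <- function(i) {          # G-run length starting exactly at i
    j <- i
    while (j <= n && ch[j] == "G") j <- j + 1L
    j - i
  }
  rec <- function(i, runs_left) {    # a run must start exactly at i
    if (i > n) return(FALSE)
    rl <- run_from(i)
    if (rl < 3L) return(FALSE)
    if (runs_left == 1L) return(TRUE)
    for (use in 3:rl) {
      for (loop in 1:7) {
        if (rec(i + use + loop, runs_left - 1L)) return(TRUE)
      }
    }
    FALSE
  }
  any(vapply(seq_len(n), function(start) rec(start, 4L), logical(1)))
}

# greedy matching of detections to ground-truth centers within `tol` px
match_spots <- function(det, truth, tol = 3) {
  tp <- 0L
  if (!nrow(det) || !nrow(truth)) return(0L)
  used <- rep(FALSE, nrow(det))
  for (i in seq_len(nrow(truth))) {
    d2 <- (det$y - truth$y[i])^2 + (det$x - truth$x[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (d2[j] <= tol^2) { used[j] <- TRUE; tp <- tp + 1L }
  }
  tp
}

# the seed-0 probe-design fixture and its design run, computed once per
# test session
.fixture_cache <- new.env(parent = emptyenv())
seed0_fixture <- function() {
  if (is.null(.fixture_cache$fx))
    .fixture_cache$fx <- endofish::generate_sequences(
      endofish::seq_fixture_spec(seed = 0))
  .fixture_cache$fx
}
seed0_design <- function() {
  if (is.null(.fixture_cache$ps))
    .fixture_cache$ps <- endofish::design_probes(seed0_fixture()$records)
  .fixture_cache$ps
}

# assemble a blob_set by hand (for mask/transect unit tests)
make_blob_set <- function(y, x, shape, sigma = 2, response = 1) {
  structure(list(blobs = data.frame(y = y, x = x,
                                    sigma = rep_len(sigma, length(y)),
                                    response = rep_len(response, length(y))),
                 source_image_id = "synthetic", dog_params = NULL,
                 image_shape = as.integer(shape)),
            class = "blob_set")
}
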