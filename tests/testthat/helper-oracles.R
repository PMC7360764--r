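# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (quadratic scans, per-position tallies) so they share
# no code path with the implementation they check.

# O(n^2) bracket matcher: for every closing character, walk left counting
# balance within its own family.
oracle_pair_map <- function(structure) {
  ch <- strsplit(structure, "")[[1L]]
  open <- c("(", "[", "{", "<", "A", "B", "C", "D")
  close <- c(")", "]", "}", ">", "a", "b", "c", "d")
  n <- length(ch)
  pair <- integer(n)
  for (i in seq_len(n)) {
    f <- match(ch[i], close)
    if (is.na(f)) next
    bal <- 1L
    j <- i - 1L
    while (j >= 1L) {
      if (ch[j] == close[f]) bal <- bal + 1L
      if (ch[j] == open[f]) {
        bal <- bal - 1L
        if (bal == 0L) break
      }
      j <- j - 1L
    }
    stopifnot(j >= 1L)
    pair[i] <- j
    pair[j] <- i
  }
  pair
}

# Random valid pair map (crossings allowed): repeatedly pair two random
# unpaired positions.
random_pair_map <- function(n, n_pairs = NULL) {
  if (is.null(n_pairs)) n_pairs <- sample.int(max(1L, n %/% 4L), 1L)
  pair <- integer(n)
  for (k in seq_len(n_pairs)) {
    free <- which(pair == 0L)
    if (length(free) < 2L) break
    ij <- sort(sample(free, 2L))
    pair[ij[1L]] <- ij[2L]
    pair[ij[2L]] <- ij[1L]
  }
  pair
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

random_structure <- function(n, ...) {
  transcript_structure("rnd", random_rna(n), random_pair_map(n, ...))
}

# Brute-force crossing test over all pair quadruples.
oracle_crossing_pairs <- function(pair) {
  i <- which(pair > seq_along(pair))
  pr <- cbind(i = i, j = pair[i])
  crossing <- rep(FALSE, nrow(pr))
  if (nrow(pr) >= 2L) {
    for (a in seq_len(nrow(pr))) {
      for (b in seq_len(nrow(pr))) {
        if (a == b) next
        if (pr[a, "i"] < pr[b, "i"] && pr[b, "i"] < pr[a, "j"] &&
            pr[a, "j"] < pr[b, "j"]) {
          crossing[a] <- TRUE
          crossing[b] <- TRUE
        }
      }
    }
  }
  pr[crossing, , drop = FALSE]
}

# Per-position read-membership tally.
oracle_coverage <- function(reads, transcript_length) {
  vapply(seq_len(transcript_length), function(i)
    sum(reads$start <= i & reads$end >= i), 0L)
}

# Naive sliding-window mismatch scan, one strand.
oracle_mismatch_hits <- function(pattern, subject, max_mismatches) {
  p <- strsplit(pattern, "")[[1L]]
  s <- strsplit(subject, "")[[1L]]
  m <- length(p)
  hits <- integer(0)
  if (length(s) < m) return(hits)
  for (st in seq_len(length(s) - m + 1L)) {
    if (sum(s[st:(st + m - 1L)] != p) <= max_mismatches)
      hits <- c(hits, st)
  }
  hits
}

# Exhaustive segment-pair scan for an intramolecular hairpin: any two
# reverse-complementary segments of length `stem` separated by >= `loop`.
oracle_has_hairpin <- function(seq, stem, loop) {
  ch <- strsplit(seq, "")[[1L]]
  comp <- c(A = "U", C = "G", G = "C", U = "A", N = "N")
  n <- length(ch)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i + stem + loop) next
      if (i + stem - 1L > n || j + stem - 1L > n) next
      a <- ch[i:(i + stem - 1L)]
      b <- ch[j:(j + stem - 1L)]
      if (all(a == rev(comp[b]))) return(TRUE)
    }
  }
  FALSE
}

# Hand CT text for a structure given sequence and pair map.
make_ct_text <- function(sequence, pair, title = "tx") {
  n <- nchar(sequence)
  ch <- strsplit(sequence, "")[[1L]]
  c(paste(n, title),
    sprintf("%d %s %d %d %d %d", 1:n, ch, 0:(n - 1L),
            c(2:n, 0L), pair, 1:n))
}
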