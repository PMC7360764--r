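## Secondary-structure input/output: connectivity tables (CT), extended
## dot-bracket (pseudoknot bracket alphabets), PARS-style probing tracks,
## and bare FASTA sequences. Everything funnels into one validated
## in-memory model, `transcript_structure`.

# Bracket families recognised in extended dot-bracket, in the order used
# when writing crossing (pseudoknotted) pair sets.
.bracket_open  <- c("(", "[", "{", "<", "A", "B", "C", "D")
.bracket_close <- c(")", "]", "}", ">", "a", "b", "c", "d")

#' Construct a validated transcript secondary structure
#'
#' The central container of the package: an RNA sequence together with its
#' per-nucleotide pairing state. Position `i` is paired with `pair[i]`
#' (1-based), or unpaired when `pair[i] == 0`. All coordinates in the
#' package are 1-based inclusive, matching the CT convention; conversion to
#' 0-based half-open happens only at BED export.
#'
#' @param transcript_id Character scalar naming the transcript.
#' @param sequence RNA sequence (string). `T` is normalised to `U` and the
#'   sequence is upper-cased; alphabet is restricted to `A,C,G,U,N`.
#' @param pair Integer vector of partner indices, `0` = unpaired.
#' @param source One of `"ct"`, `"dotbracket"`, `"pars"`, `"synthetic"`.
#' @return An object of class `transcript_structure` with fields
#'   `transcript_id`, `sequence`, `pair`, `source`.
#' @examples
#' s <- transcript_structure("tx", "GGGGAAAACCCC",
#'                           c(12, 11, 10, 9, 0, 0, 0, 0, 4, 3, 2, 1))
#' @export
transcript_structure <- function(transcript_id, sequence, pair,
                                 source = "synthetic") {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L)
  sequence <- normalize_rna(sequence)
  pair <- as.integer(pair)
  n <- nchar(sequence)
  if (length(pair) != n)
    stop("sequence length (", n, ") != pair vector length (",
         length(pair), ")")
  source <- match.arg(source, c("ct", "dotbracket", "pars", "synthetic"))
  obj <- structure(
    list(transcript_id = transcript_id, sequence = sequence,
         pair = pair, source = source),
    class = "transcript_structure")
  validate_structure(obj)
  obj
}

#' @export
print.transcript_structure <- function(x, ...) {
  n <- nchar(x$sequence)
  cat("transcript_structure '", x$transcript_id, "' (", n, " nt, ",
      sum(x$pair > 0L) %/% 2L, " base pairs, source=", x$source, ")\n",
      sep = "")
  invisible(x)
}

#' @export
length.transcript_structure <- function(x) nchar(x$sequence)

# Enforce the structural invariants: symmetric pairing, no self-pairing,
# partners in range. Called by every constructor/parser.
validate_structure <- function(s) {
  p <- s$pair
  n <- length(p)
  if (any(is.na(p))) stop("pair vector contains NA")
  if (any(p < 0L | p > n))
    stop("partner index out of range at position ",
         which(p < 0L | p > n)[1L])
  if (any(p == seq_len(n)))
    stop("self-pairing at position ", which(p == seq_len(n))[1L])
  paired <- which(p > 0L)
  bad <- paired[p[p[paired]] != paired]
  if (length(bad))
    stop("asymmetric pairing at position ", bad[1L],
         " (pair[", bad[1L], "] = ", p[bad[1L]], " but pair[",
         p[bad[1L]], "] = ", p[p[bad[1L]]], ")")
  invisible(s)
}

#' Normalise an RNA/DNA sequence string to the RNA alphabet
#'
#' Upper-cases and converts `T` to `U`; rejects characters outside
#' `A,C,G,U,N`.
#' @param sequence Character scalar.
#' @return Normalised sequence string.
#' @export
normalize_rna <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- chartr("t", "u", toupper(sequence))
  s <- chartr("T", "U", s)
  bad <- setdiff(unique(strsplit(s, "")[[1L]]), c("A", "C", "G", "U", "N"))
  if (length(bad))
    stop("invalid sequence character(s): ", paste(bad, collapse = ", "))
  s
}

# Character vector view of the sequence.
seq_chars <- function(s) strsplit(s$sequence, "")[[1L]]

#' Parse a connectivity-table (CT) file
#'
#' The CT layout is a header line whose first field is the structure
#' length, followed by one line per nucleotide with six columns: index,
#' base, previous index, next index, partner index (0 = unpaired), natural
#' numbering. Files may concatenate several structures; by default the
#' first (minimum-free-energy) structure is returned.
#'
#' @param text Either a path to a CT file or the CT content as a character
#'   vector of lines (or a single string with embedded newlines).
#' @param index Which structure to take from a multi-structure file.
#' @param transcript_id Optional id; defaults to the header title or
#'   `"transcript"`.
#' @return A [transcript_structure].
#' @export
parse_ct <- function(text, index = 1L, transcript_id = NULL) {
  lines <- .as_lines(text)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty CT input")
  i <- 1L
  struct_no <- 0L
  repeat {
    if (i > length(lines)) stop("CT structure index ", index, " not found")
    header <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    n <- suppressWarnings(as.integer(header[1L]))
    if (is.na(n) || n < 1L)
      stop("malformed CT header at line ", i, ": '", lines[i], "'")
    struct_no <- struct_no + 1L
    if (struct_no == index) break
    i <- i + n + 1L
  }
  title <- if (length(header) > 1L)
    paste(header[-1L], collapse = " ") else "transcript"
  if (i + n > length(lines))
    stop("CT body truncated: header declares ", n, " bases but only ",
         length(lines) - i, " lines follow")
  body <- lines[(i + 1L):(i + n)]
  bases <- character(n)
  pair <- integer(n)
  for (k in seq_len(n)) {
    f <- strsplit(trimws(body[k]), "\\s+")[[1L]]
    if (length(f) < 5L)
      stop("malformed CT line ", i + k, ": '", body[k], "'")
    idx <- suppressWarnings(as.integer(f[1L]))
    if (is.na(idx) || idx != k)
      stop("CT line ", i + k, ": index ", f[1L], " where ", k,
           " expected")
    bases[k] <- f[2L]
    pk <- suppressWarnings(as.integer(f[5L]))
    if (is.na(pk))
      stop("CT line ", i + k, ": non-integer partner column '", f[5L], "'")
    if (pk < 0L || pk > n)
      stop("CT line ", i + k, ": partner index ", pk, " out of range 0..",
           n)
    pair[k] <- pk
  }
  bad <- which(pair > 0L & pair[pmax(pair, 1L)] != seq_len(n))
  if (length(bad))
    stop("CT asymmetric pairing: line for position ", bad[1L],
         " claims partner ", pair[bad[1L]], " but position ",
         pair[bad[1L]], " lists partner ", pair[pair[bad[1L]]])
  transcript_structure(
    transcript_id %||% title,
    paste(bases, collapse = ""), pair, source = "ct")
}

#' Write a structure as a CT file
#'
#' @param s A [transcript_structure].
#' @param file Optional path; when `NULL` the CT text is returned as a
#'   character vector of lines.
#' @export
write_ct <- function(s, file = NULL) {
  n <- length(s)
  ch <- seq_chars(s)
  lines <- c(
    paste(n, s$transcript_id),
    sprintf("%d %s %d %d %d %d", seq_len(n), ch, seq_len(n) - 1L,
            c(seq_len(n - 1L) + 1L, 0L), s$pair, seq_len(n)))
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(file)
}

#' Parse an extended dot-bracket string
#'
#' Each bracket family (`()`, `[]`, `{}`, `<>`, `Aa`..`Dd`) is matched
#' independently with its own stack, so crossing (pseudoknotted) pair sets
#' are representable. `.` (and `-`/`:` as synonyms) mean unpaired.
#'
#' @param sequence RNA sequence string.
#' @param structure Dot-bracket string of the same length.
#' @param transcript_id Transcript id.
#' @return A [transcript_structure].
#' @export
parse_dotbracket <- function(sequence, structure,
                             transcript_id = "transcript") {
  sequence <- normalize_rna(sequence)
  if (nchar(sequence) != nchar(structure))
    stop("sequence length (", nchar(sequence),
         ") != structure length (", nchar(structure), ")")
  ch <- strsplit(structure, "")[[1L]]
  n <- length(ch)
  pair <- integer(n)
  stacks <- vector("list", length(.bracket_open))
  for (i in seq_len(n)) {
    c_i <- ch[i]
    if (c_i %in% c(".", "-", ":")) next
    fo <- match(c_i, .bracket_open)
    fc <- match(c_i, .bracket_close)
    if (!is.na(fo)) {
      stacks[[fo]] <- c(stacks[[fo]], i)
    } else if (!is.na(fc)) {
      st <- stacks[[fc]]
      if (!length(st))
        stop("unbalanced '", c_i, "' at position ", i,
             ": no matching opener")
      j <- st[length(st)]
      stacks[[fc]] <- st[-length(st)]
      pair[i] <- j
      pair[j] <- i
    } else {
      stop("unrecognised structure character '", c_i, "' at position ", i)
    }
  }
  left_open <- which(vapply(stacks, length, 1L) > 0L)
  if (length(left_open))
    stop("unbalanced '", .bracket_open[left_open[1L]],
         "': ", length(stacks[[left_open[1L]]]), " opener(s) never closed")
  transcript_structure(transcript_id, sequence, pair,
                       source = "dotbracket")
}

#' Render a structure as an extended dot-bracket string
#'
#' Pairs are assigned greedily to bracket families: each pair goes to the
#' first family none of whose already-assigned pairs it crosses, so a
#' nested structure uses only `()` and each additional crossing pair set
#' takes the next family (`[]`, `{}`, ...).
#'
#' @param s A [transcript_structure].
#' @return A dot-bracket string; `parse_dotbracket()` on it reproduces
#'   `s$pair` exactly.
#' @export
write_dotbracket <- function(s) {
  n <- length(s)
  out <- rep(".", n)
  pairs <- structure_pairs(s)
  if (!nrow(pairs)) return(paste(out, collapse = ""))
  fam_pairs <- vector("list", length(.bracket_open))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    placed <- FALSE
    for (f in seq_along(fam_pairs)) {
      fp <- fam_pairs[[f]]
      crosses <- FALSE
      if (!is.null(fp) && nrow(fp)) {
        crosses <- any((fp$i < i & i < fp$j & fp$j < j) |
                       (i < fp$i & fp$i < j & j < fp$j))
      }
      if (!crosses) {
        fam_pairs[[f]] <- rbind(fp, data.frame(i = i, j = j))
        out[i] <- .bracket_open[f]
        out[j] <- .bracket_close[f]
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("structure needs more than ", length(.bracket_open),
           " crossing bracket families")
  }
  paste(out, collapse = "")
}

#' Base pairs of a structure as a data frame
#'
#' @param s A [transcript_structure].
#' @return `data.frame` with columns `i < j`, one row per pair, sorted by
#'   `i`.
#' @export
structure_pairs <- function(s) {
  p <- s$pair
  i <- which(p > seq_along(p))
  data.frame(i = i, j = p[i])
}

#' Parse a PARS-style structure-probing score track
#'
#' Input rows are `(transcript_id, position, score)`, tab- or
#' whitespace-separated, positions 1-based and not necessarily contiguous.
#' Scores follow the PARS convention: positive means double-stranded
#' propensity (V1/S1 ratio), negative single-stranded. Set
#' `invert = TRUE` for probing chemistries with the opposite sign.
#'
#' @param text Path or character lines.
#' @param length Transcript length; defaults to the maximum position seen.
#' @param invert Flip the sign of all scores.
#' @return An object of class `probing_track`: `transcript_id`, `scores`
#'   (numeric, `NA` at masked positions), `mask` (`TRUE` = missing).
#' @export
parse_probing_track <- function(text, length = NULL, invert = FALSE) {
  lines <- .as_lines(text)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("empty probing track")
  df <- utils::read.table(text = lines, sep = "", header = FALSE,
                          col.names = c("transcript_id", "pos", "score"),
                          colClasses = c("character", "integer",
                                         "character"))
  score <- suppressWarnings(as.numeric(df$score))
  if (anyNA(score))
    stop("non-numeric score '", df$score[which(is.na(score))[1L]],
         "' at position ", df$pos[which(is.na(score))[1L]])
  ids <- unique(df$transcript_id)
  if (length(ids) > 1L)
    stop("probing track mixes transcripts: ", paste(ids, collapse = ", "))
  if (anyDuplicated(df$pos))
    stop("duplicate position ", df$pos[duplicated(df$pos)][1L],
         " in probing track")
  if (any(df$pos < 1L)) stop("positions must be 1-based positive")
  n <- if (is.null(length)) max(df$pos) else as.integer(length)
  if (max(df$pos) > n)
    stop("position ", max(df$pos), " exceeds declared length ", n)
  scores <- rep(NA_real_, n)
  scores[df$pos] <- if (invert) -score else score
  structure(list(transcript_id = ids, scores = scores,
                 mask = is.na(scores)),
            class = "probing_track")
}

#' @export
print.probing_track <- function(x, ...) {
  cat("probing_track '", x$transcript_id, "' (", length(x$scores),
      " nt, ", sum(x$mask), " masked)\n", sep = "")
  invisible(x)
}

#' Construct a probing track from scores in memory
#' @param transcript_id Transcript id.
#' @param scores Numeric vector; `NA` marks missing positions.
#' @export
probing_track <- function(transcript_id, scores) {
  structure(list(transcript_id = transcript_id,
                 scores = as.numeric(scores),
                 mask = is.na(scores)),
            class = "probing_track")
}

#' Write a probing track as TSV
#' @param track A `probing_track`.
#' @param file Path, or `NULL` to return lines.
#' @export
write_probing_track <- function(track, file = NULL) {
  keep <- !track$mask
  lines <- sprintf("%s\t%d\t%g", track$transcript_id,
                   which(keep), track$scores[keep])
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(file)
}

#' Read transcript sequences from a FASTA file
#'
#' @param file FASTA path.
#' @return Named character vector of RNA sequences (T normalised to U).
#' @export
read_transcript_fasta <- function(file) {
  set <- Biostrings::readBStringSet(file)
  out <- vapply(as.character(set), normalize_rna, "")
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences as FASTA
#' @param sequences Named character vector.
#' @param file Path.
#' @export
write_fasta <- function(sequences, file) {
  Biostrings::writeXStringSet(
    Biostrings::RNAStringSet(sequences), file)
  invisible(file)
}

.as_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    return(readLines(text, warn = FALSE))
  unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
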