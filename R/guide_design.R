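## Spacer candidate enumeration and scoring. A guide is ranked by how many
## of its protospacer nucleotides fall in single-stranded (SS) target
## regions, with special weight on the 8-base central seed (guide
## positions 11-18 on a 28-mer): full seed-SS complementarity alone is
## sufficient for the efficient class.

#' Design configuration for guide enumeration
#'
#' Defaults encode the empirical design rules: 28-nt spacers (20-28
#' tolerated), efficiency class boundaries at <=10 SS-complementary
#' nucleotides (poor) and >=18 (efficient), full 8/8 central-seed SS
#' complementarity sufficient for the efficient class, a soft
#' informational flag on a 3' G protospacer-flanking site (LshCas13a
#' profile; no hard PFS restriction), and a BbsI (GAAGAC) 5' cloning
#' adapter. Filter thresholds (hairpin stem >=5 bp with >=3 nt loop,
#' self-dimer run >=8 nt, homopolymer >5 nt) are screening defaults and
#' fully configurable.
#'
#' @param spacer_length Guide spacer length in nt, 20-28.
#' @param step Enumeration step along the transcript (nt).
#' @param poor_max_ss Maximum total SS-complementary count still classed
#'   poor (when the seed is not fully SS).
#' @param efficient_min_ss Minimum total SS-complementary count for the
#'   efficient class via the length route.
#' @param seed_full Seed SS count deemed a full seed (window width).
#' @param pfs_profile PFS ortholog profile; `"LshCas13a"` soft-flags a
#'   3' G, `"none"` never flags.
#' @param adapter_fwd,adapter_rev 5' DNA adapters for the forward and
#'   reverse cloning oligos; the defaults carry the BbsI recognition site
#'   GAAGAC.
#' @param hairpin_stem_min Minimum self-reverse-complementary stem (bp)
#'   for the `self_complementary` flag.
#' @param hairpin_loop_min Minimum separation (nt) between the two stem
#'   arms.
#' @param dimer_run_min Minimum self reverse-complement alignment run (nt)
#'   for the `dimer_prone` flag.
#' @param homopolymer_max Longest tolerated homopolymer run (nt).
#' @return A list of class `design_config`.
#' @export
design_config <- function(spacer_length = 28L, step = 1L,
                          poor_max_ss = 10L, efficient_min_ss = 18L,
                          seed_full = 8L,
                          pfs_profile = c("LshCas13a", "none"),
                          adapter_fwd = "GAAGACTTGTGG",
                          adapter_rev = "GAAGACTTAAAC",
                          hairpin_stem_min = 5L, hairpin_loop_min = 3L,
                          dimer_run_min = 8L, homopolymer_max = 5L) {
  spacer_length <- as.integer(spacer_length)
  validate_spacer_length(spacer_length)
  stopifnot(step >= 1L, poor_max_ss < efficient_min_ss,
            efficient_min_ss <= spacer_length, seed_full == 8L)
  structure(list(
    spacer_length = spacer_length, step = as.integer(step),
    poor_max_ss = as.integer(poor_max_ss),
    efficient_min_ss = as.integer(efficient_min_ss),
    seed_full = as.integer(seed_full),
    pfs_profile = match.arg(pfs_profile),
    adapter_fwd = adapter_fwd, adapter_rev = adapter_rev,
    hairpin_stem_min = as.integer(hairpin_stem_min),
    hairpin_loop_min = as.integer(hairpin_loop_min),
    dimer_run_min = as.integer(dimer_run_min),
    homopolymer_max = as.integer(homopolymer_max)),
    class = "design_config")
}

#' Validate a spacer length
#'
#' Spacer lengths of 20-28 nt are tolerated by Cas13 provided the central
#' seed is retained; anything outside that range is rejected.
#' @param length Proposed spacer length.
#' @export
validate_spacer_length <- function(length) {
  if (length < 20L || length > 28L)
    stop("spacer length ", length, " outside the tolerated range 20-28 nt")
  invisible(as.integer(length))
}

#' Central-seed window on the guide
#'
#' The 8 central bases of the guide; for a 28-mer these are guide
#' positions 11-18. Shorter guides keep a centred 8-mer:
#' `start = floor((length - 8) / 2) + 1`.
#'
#' @param length Guide length (>= 8).
#' @return Integer vector `c(start, end)` of guide positions, width 8.
#' @export
central_seed_window <- function(length) {
  length <- as.integer(length)
  if (length < 8L)
    stop("guide length ", length, " shorter than the 8-base central seed")
  start <- (length - 8L) %/% 2L + 1L
  c(start = start, end = start + 7L)
}

# Map guide positions [gs, ge] to transcript positions, given the
# protospacer span [ps, pe]. Guide position k binds antiparallel to
# transcript position pe - k + 1.
.guide_to_transcript <- function(gs, ge, ps, pe) {
  c(pe - ge + 1L, pe - gs + 1L)
}

#' SS-complementarity scores for one protospacer window
#'
#' Counts protospacer nucleotides called SS, overall and within the
#' positions opposite the guide's central-seed window (assuming perfect
#' antiparallel complementarity). Unknown-state positions never count as
#' SS; their number is reported separately.
#'
#' @param start,end Protospacer span, 1-based inclusive on the transcript.
#' @param state Strand-state vector for the transcript.
#' @return List `ss_complement_count`, `central_seed_ss_count`,
#'   `unknown_count`.
#' @export
score_ss_overlap <- function(start, end, state) {
  n <- length(state)
  if (start < 1L || end > n || start > end)
    stop("protospacer [", start, ",", end, "] outside transcript 1..", n)
  len <- end - start + 1L
  win <- state[start:end]
  seed <- central_seed_window(len)
  tr <- .guide_to_transcript(seed[1L], seed[2L], start, end)
  seed_win <- state[tr[1L]:tr[2L]]
  list(ss_complement_count = sum(win == "SS"),
       central_seed_ss_count = sum(seed_win == "SS"),
       unknown_count = sum(win == "unknown"))
}

#' Classify predicted guide efficiency
#'
#' `efficient` when the central seed is fully SS-complementary (8/8) or
#' the total SS-complementary count reaches `efficient_min_ss` (default
#' 18); `poor` when the total count is at most `poor_max_ss` (default 10)
#' and the seed is not full; `intermediate` otherwise.
#'
#' @param ss_complement_count Total SS-complementary nucleotides.
#' @param central_seed_ss_count SS-complementary nucleotides opposite the
#'   central seed (0-8).
#' @param config A [design_config()].
#' @return `"efficient"`, `"intermediate"` or `"poor"`.
#' @export
classify_efficiency <- function(ss_complement_count,
                                central_seed_ss_count,
                                config = design_config()) {
  if (central_seed_ss_count == config$seed_full ||
      ss_complement_count >= config$efficient_min_ss) return("efficient")
  if (ss_complement_count <= config$poor_max_ss) return("poor")
  "intermediate"
}

#' Protospacer flanking sites (PFS) of a candidate
#'
#' The transcript nucleotides immediately 5' and 3' of the protospacer;
#' `N` at a transcript edge. Under the default LshCas13a profile a 3' G is
#' soft-flagged (slightly reduced knockdown reported for G-PFS); the flag
#' is informational and never filters a candidate.
#'
#' @param sequence Transcript sequence string.
#' @param start,end Protospacer span.
#' @param config A [design_config()].
#' @return List `pfs_5prime`, `pfs_3prime`, `pfs_flag`.
#' @export
extract_pfs <- function(sequence, start, end, config = design_config()) {
  n <- nchar(sequence)
  p5 <- if (start > 1L) substr(sequence, start - 1L, start - 1L) else "N"
  p3 <- if (end < n) substr(sequence, end + 1L, end + 1L) else "N"
  flag <- config$pfs_profile == "LshCas13a" && p3 == "G"
  list(pfs_5prime = p5, pfs_3prime = p3, pfs_flag = flag)
}

#' Reverse complement in the RNA alphabet
#' @param sequence RNA string.
#' @export
rna_reverse_complement <- function(sequence) {
  as.character(Biostrings::reverseComplement(
    Biostrings::RNAString(sequence)))
}

#' Sequence-quality filters for a spacer
#'
#' Flags spacers prone to intramolecular hairpins
#' (`self_complementary`: two reverse-complementary segments of at least
#' `hairpin_stem_min` nt separated by at least `hairpin_loop_min` nt),
#' self-dimers (`dimer_prone`: longest complementary alignment of the
#' spacer against its own reverse complement at least `dimer_run_min`
#' nt), and low complexity (`low_complexity`: a homopolymer run longer
#' than `homopolymer_max`).
#'
#' @param spacer Spacer sequence (RNA alphabet).
#' @param config A [design_config()].
#' @return Character vector of triggered flags (possibly empty).
#' @export
sequence_filters <- function(spacer, config = design_config()) {
  spacer <- normalize_rna(spacer)
  flags <- character(0)
  if (has_hairpin(spacer, config$hairpin_stem_min, config$hairpin_loop_min))
    flags <- c(flags, "self_complementary")
  if (longest_selfdimer_run(spacer) >= config$dimer_run_min)
    flags <- c(flags, "dimer_prone")
  if (max_homopolymer_run(spacer) > config$homopolymer_max)
    flags <- c(flags, "low_complexity")
  flags
}

# Two reverse-complementary segments of exactly `stem` nt with >= `loop`
# nt between them; any longer stem contains one of this length.
has_hairpin <- function(seq, stem, loop) {
  n <- nchar(seq)
  if (n < 2L * stem + loop) return(FALSE)
  ch <- strsplit(seq, "")[[1L]]
  rc1 <- c(A = "U", C = "G", G = "C", U = "A", N = "N")
  for (i in seq_len(n - 2L * stem - loop + 1L)) {
    a <- ch[i:(i + stem - 1L)]
    for (j in (i + stem + loop):(n - stem + 1L)) {
      b <- ch[j:(j + stem - 1L)]
      if (all(rev(rc1[b]) == a)) return(TRUE)
    }
  }
  FALSE
}

# Longest run of consecutive Watson-Crick matches in any ungapped
# alignment of the spacer with its own reverse complement (self-dimer).
longest_selfdimer_run <- function(seq) {
  a <- strsplit(seq, "")[[1L]]
  b <- strsplit(rna_reverse_complement(seq), "")[[1L]]
  n <- length(a)
  best <- 0L
  # offsets of b relative to a; run of equalities = complementary run
  for (off in (-(n - 1L)):(n - 1L)) {
    run <- 0L
    for (i in seq_len(n)) {
      j <- i + off
      if (j >= 1L && j <= n && a[i] == b[j] && a[i] != "N") {
        run <- run + 1L
        if (run > best) best <- run
      } else run <- 0L
    }
  }
  best
}

# Longest homopolymer run.
max_homopolymer_run <- function(seq) {
  r <- rle(strsplit(seq, "")[[1L]])
  max(r$lengths)
}

#' Scan background sequences for protospacer occurrences
#'
#' Local similarity search standing in for a genome-wide web search: finds
#' all occurrences of the protospacer, sense and antisense, in a set of
#' background sequences with at most `max_mismatches` substitutions
#' (no indels). Uses Biostrings pattern matching.
#'
#' @param protospacer Protospacer sequence (transcript sense, RNA or DNA).
#' @param background Named character vector of sequences, or a FASTA path.
#' @param max_mismatches Maximum substitutions per hit.
#' @return `data.frame` with `subject`, `start`, `end`, `strand`,
#'   `mismatches`, one row per hit.
#' @export
off_target_scan <- function(protospacer, background, max_mismatches = 0L) {
  if (is.character(background) && length(background) == 1L &&
      file.exists(background))
    background <- read_transcript_fasta(background)
  if (!length(background)) stop("empty background")
  if (is.null(names(background)))
    names(background) <- paste0("seq", seq_along(background))
  pat <- Biostrings::RNAString(normalize_rna(protospacer))
  subjects <- Biostrings::RNAStringSet(
    vapply(background, normalize_rna, ""))
  hits <- list()
  for (strand in c("+", "-")) {
    p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
    m <- Biostrings::vmatchPattern(p, subjects,
                                   max.mismatch = max_mismatches)
    for (k in seq_along(m)) {
      if (!length(m[[k]])) next
      st <- BiocGenerics::start(m[[k]])
      en <- BiocGenerics::end(m[[k]])
      mm <- vapply(seq_along(st), function(h) {
        sub <- Biostrings::subseq(subjects[[k]], st[h], en[h])
        sum(strsplit(as.character(sub), "")[[1L]] !=
            strsplit(as.character(p), "")[[1L]])
      }, 0L)
      hits[[length(hits) + 1L]] <- data.frame(
        subject = names(background)[k], start = st, end = en,
        strand = strand, mismatches = mm, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(subject = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Cloning oligos for a spacer
#'
#' Renders the DNA oligo pair for Golden-Gate cloning: the configured 5'
#' adapters (default carrying the BbsI site GAAGAC) prepended to the
#' spacer and to its reverse complement. Stripping the adapter recovers
#' the spacer exactly.
#'
#' @param spacer Spacer sequence (RNA alphabet).
#' @param config A [design_config()].
#' @return List `forward`, `reverse` (DNA strings).
#' @export
render_cloning_oligos <- function(spacer, config = design_config()) {
  dna <- chartr("U", "T", normalize_rna(spacer))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(dna)))
  list(forward = paste0(config$adapter_fwd, dna),
       reverse = paste0(config$adapter_rev, rc))
}

#' Enumerate and rank spacer candidates along a transcript
#'
#' Slides a window of `config$spacer_length` along the transcript at
#' `config$step`, scoring every window for SS complementarity (total and
#' central seed), efficiency class, PFS, junction coverage, pseudoknot
#' bases and sequence filters. Candidates are sorted by efficiency class
#' (efficient first), then central-seed SS count, then total SS count,
#' descending, with ties broken by protospacer start ascending -- a
#' stable, deterministic order.
#'
#' @param sequence Transcript sequence string.
#' @param state Strand-state vector (from [state_from_structure()] or
#'   [state_from_probing()]).
#' @param config A [design_config()].
#' @param transcript_id Transcript id for the output table.
#' @param knots Optional `pseudoknot_annotation` for `knot_base_count`.
#' @param background Optional background sequences for the off-target
#'   scan.
#' @param max_mismatches Mismatch allowance for the off-target scan.
#' @return `data.frame` of class `guide_candidates`, one row per window.
#' @export
enumerate_candidates <- function(sequence, state,
                                 config = design_config(),
                                 transcript_id = "transcript",
                                 knots = NULL, background = NULL,
                                 max_mismatches = 0L) {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  len <- config$spacer_length
  if (n < len)
    stop("transcript (", n, " nt) shorter than spacer length ", len)
  stopifnot(length(state) == n)
  seg <- segment_regions(state)
  boundaries <- seg$junctions$boundary
  seed <- central_seed_window(len)
  starts <- seq.int(1L, n - len + 1L, by = config$step)
  rows <- lapply(starts, function(ps) {
    pe <- ps + len - 1L
    sc <- score_ss_overlap(ps, pe, state)
    pfs <- extract_pfs(sequence, ps, pe, config)
    proto <- substr(sequence, ps, pe)
    spacer <- rna_reverse_complement(proto)
    flags <- sequence_filters(spacer, config)
    if (!is.null(background)) {
      hits <- off_target_scan(proto, background, max_mismatches)
      # hits outside the target locus only
      off <- hits[!(hits$strand == "+" & hits$start == ps &
                    hits$end == pe &
                    hits$subject == transcript_id), , drop = FALSE]
      if (nrow(off)) flags <- c(flags, "off_target_hit")
    }
    data.frame(
      transcript_id = transcript_id,
      protospacer_start = ps, protospacer_end = pe, length = len,
      spacer_sequence = spacer,
      spacer_dna = chartr("U", "T", spacer),
      ss_complement_count = sc$ss_complement_count,
      central_seed_start = seed[1L], central_seed_end = seed[2L],
      central_seed_ss_count = sc$central_seed_ss_count,
      unknown_count = sc$unknown_count,
      pfs_5prime = pfs$pfs_5prime, pfs_3prime = pfs$pfs_3prime,
      pfs_flag = pfs$pfs_flag,
      covers_junction = any(boundaries >= ps & boundaries < pe),
      knot_base_count = if (is.null(knots)) 0L else
        knot_bases_in_window(knots, ps, pe),
      filter_flags = paste(flags, collapse = ","),
      efficiency_class = classify_efficiency(
        sc$ss_complement_count, sc$central_seed_ss_count, config),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  cls_rank <- match(out$efficiency_class,
                    c("efficient", "intermediate", "poor"))
  ord <- order(cls_rank, -out$central_seed_ss_count,
               -out$ss_complement_count, out$protospacer_start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("guide_candidates", "data.frame")
  out
}

#' Export protospacers as BED
#'
#' 0-based half-open coordinates; the score column carries the
#' central-seed SS count, the name the efficiency class.
#' @param candidates A `guide_candidates` table.
#' @param file Path, or `NULL` for lines.
#' @export
export_candidates_bed <- function(candidates, file = NULL) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t+",
                   candidates$transcript_id,
                   candidates$protospacer_start - 1L,
                   candidates$protospacer_end,
                   candidates$efficiency_class,
                   candidates$central_seed_ss_count)
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(file)
}

#' Oligo order sheet for a candidate table
#' @param candidates A `guide_candidates` table.
#' @param config A [design_config()].
#' @return `data.frame` with `name`, `forward`, `reverse` DNA oligos.
#' @export
oligo_order_sheet <- function(candidates, config = design_config()) {
  oligos <- lapply(candidates$spacer_sequence, render_cloning_oligos,
                   config = config)
  data.frame(
    name = sprintf("%s_%d_%d", candidates$transcript_id,
                   candidates$protospacer_start,
                   candidates$protospacer_end),
    forward = vapply(oligos, `[[`, "", "forward"),
    reverse = vapply(oligos, `[[`, "", "reverse"),
    stringsAsFactors = FALSE)
}
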