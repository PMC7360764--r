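## Deterministic synthetic fixtures: transcripts with fully known
## secondary structure, probing tracks derived from that structure, and
## treatment/control read sets with cleavage planted at known loci. All
## generators are pure functions of (parameters, seed).

# Run `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so generators never perturb user code.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Build a transcript realising a stem/loop design
#'
#' The design is a token vector: `"s<N>"` opens a helix of N base pairs,
#' `"l<N>"` inserts an unpaired run of N nt, `"e"` closes the innermost
#' open helix (emitting its complementary strand); helices still open at
#' the end are closed automatically in last-in-first-out order, so
#' `c("s10","l20")` yields a 40-nt hairpin with the loop at positions
#' 11-30. Stem sequences are drawn uniformly with GC balancing (no
#' homopolymer-prone skew); loop sequences are drawn from all four bases.
#' Optional crossing pairs turn loop positions into a pseudoknot: each
#' row `(i, j)` of `knot_pairs` pairs two positions that must be unpaired
#' in the design, and the sequence is made complementary there.
#'
#' @param design Character token vector, e.g. `c("s10","l20")`.
#' @param seed Integer seed; identical seed and parameters give
#'   byte-identical output.
#' @param transcript_id Id for the generated transcript.
#' @param knot_pairs Optional 2-column matrix/data.frame of positions to
#'   pair across the design (creates crossing pairs).
#' @return A [transcript_structure] with `source = "synthetic"`.
#' @export
make_structured_transcript <- function(design, seed = 1L,
                                       transcript_id = "synthetic_tx",
                                       knot_pairs = NULL) {
  tokens <- lapply(design, function(t) {
    if (t == "e") return(list(op = "e", n = 0L))
    op <- substr(t, 1L, 1L)
    n <- suppressWarnings(as.integer(substring(t, 2L)))
    if (!op %in% c("s", "l") || is.na(n) || n < 1L)
      stop("bad design token '", t, "'")
    list(op = op, n = n)
  })
  db <- character(0)
  stack <- list()
  for (tk in tokens) {
    if (tk$op == "s") {
      db <- c(db, rep("(", tk$n))
      stack[[length(stack) + 1L]] <- tk$n
    } else if (tk$op == "l") {
      db <- c(db, rep(".", tk$n))
    } else {
      if (!length(stack)) stop("design token 'e' with no open stem")
      db <- c(db, rep(")", stack[[length(stack)]]))
      stack[[length(stack)]] <- NULL
    }
  }
  while (length(stack)) {
    db <- c(db, rep(")", stack[[length(stack)]]))
    stack[[length(stack)]] <- NULL
  }
  n <- length(db)
  if (n < 40L) stop("design yields only ", n, " nt; need >= 40")
  # pair map from the bracket skeleton
  skel <- parse_dotbracket(strrep("A", n), paste(db, collapse = ""))
  pair <- skel$pair
  if (!is.null(knot_pairs)) {
    kp <- as.matrix(knot_pairs)
    for (r in seq_len(nrow(kp))) {
      i <- kp[r, 1L]; j <- kp[r, 2L]
      if (pair[i] != 0L || pair[j] != 0L)
        stop("knot pair (", i, ",", j, ") touches an already-paired",
             " position")
      pair[i] <- j; pair[j] <- i
    }
  }
  comp <- c(A = "U", U = "A", C = "G", G = "C")
  seqv <- with_seed(seed, {
    s <- character(n)
    for (i in seq_len(n)) {
      if (nzchar(s[i])) next
      if (pair[i] > i) {
        # balanced GC/AU draw keeps stems complementary and mixed
        s[i] <- sample(c("A", "C", "G", "U"), 1L)
        s[pair[i]] <- comp[s[i]]
      } else if (pair[i] == 0L) {
        s[i] <- sample(c("A", "C", "G", "U"), 1L)
      }
    }
    s
  })
  transcript_structure(transcript_id, paste(seqv, collapse = ""), pair,
                       source = "synthetic")
}

#' Simulate a structure-probing score track from a known structure
#'
#' Emulates a PARS-style experiment: the noise-free score is +1 at paired
#' and -1 at unpaired positions, Gaussian noise of standard deviation
#' `noise_sd` is added, and a fraction of positions is masked (missing
#' data). With `noise_sd = 0`, [state_from_probing()] at threshold 0
#' recovers the true strand state at every unmasked position; with noise,
#' per-position recovery accuracy is the normal tail probability
#' `pnorm(1 / noise_sd)`.
#'
#' @param s A [transcript_structure].
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param masked_fraction Fraction of positions masked at random.
#' @param seed Integer seed.
#' @return A `probing_track`.
#' @export
simulate_probing <- function(s, noise_sd = 0.5, masked_fraction = 0.05,
                             seed = 1L) {
  stopifnot(noise_sd >= 0, masked_fraction >= 0, masked_fraction < 1)
  n <- length(s)
  base <- ifelse(s$pair > 0L, 1, -1)
  with_seed(seed, {
    scores <- base + stats::rnorm(n, 0, noise_sd)
    if (masked_fraction > 0) {
      n_mask <- floor(masked_fraction * n)
      if (n_mask > 0L) scores[sample.int(n, n_mask)] <- NA_real_
    }
    probing_track(s$transcript_id, scores)
  })
}

#' Simulate treatment and control read sets with planted cleavage
#'
#' Control reads start uniformly along the transcript with log-normal
#' lengths (loosely Nanopore-like) truncated to `[min_read_length,
#' transcript length]`. Treatment reads are the same reads except at
#' planted cleavage loci, under one of two models:
#'
#' * `"truncate"` (default): a read spanning a locus is, with probability
#'   `cleavage_efficiency`, truncated at the locus -- the portion 3' of
#'   the cut is lost, as when the downstream fragment is degraded. The
#'   coverage deficit therefore extends up to about one read length 3' of
#'   each locus.
#' * `"fragment"`: the cut splits the read in two; both fragments are
#'   retained (with new read ids) when at least `min_fragment` nt long,
#'   and the cut nucleotide itself is excised. The coverage deficit is
#'   then confined to the locus.
#'
#' MAPQ values are drawn from a two-component mixture (low: uniform
#' 0-30, high: uniform 31-60) so the mapping-quality filter is
#' exercised; a read keeps its MAPQ through truncation or fragmentation.
#'
#' @param s A [transcript_structure] (only its length and id are used).
#' @param cleavage_loci Integer positions of planted cuts (possibly
#'   empty).
#' @param n_reads Reads per sample.
#' @param cleavage_efficiency Probability a locus-spanning read is cut at
#'   that locus.
#' @param model `"truncate"` or `"fragment"` (see above).
#' @param min_fragment Shortest fragment retained under the fragment
#'   model.
#' @param read_length_meanlog,read_length_sdlog Log-normal length
#'   parameters.
#' @param min_read_length Lower truncation of read length (capped at the
#'   transcript length).
#' @param low_mapq_fraction Mixture weight of the low-MAPQ component.
#' @param seed Integer seed.
#' @return List of class `synthetic_experiment`: `treatment`, `control`
#'   (alignment `data.frame`s), `manifest` (ground truth: loci,
#'   parameters, seed).
#' @export
simulate_reads <- function(s, cleavage_loci = integer(0),
                           n_reads = 10000L, cleavage_efficiency = 0.9,
                           model = c("truncate", "fragment"),
                           min_fragment = 30L,
                           read_length_meanlog = log(150),
                           read_length_sdlog = 0.35,
                           min_read_length = 100L,
                           low_mapq_fraction = 0.15, seed = 1L) {
  n <- length(s)
  model <- match.arg(model)
  stopifnot(all(cleavage_loci >= 1L), all(cleavage_loci <= n),
            cleavage_efficiency >= 0, cleavage_efficiency <= 1)
  min_len <- min(min_read_length, n)
  with_seed(seed, {
    start <- sample.int(n, n_reads, replace = TRUE)
    len <- pmin(pmax(round(stats::rlnorm(n_reads, read_length_meanlog,
                                         read_length_sdlog)),
                     min_len), n)
    end <- pmin(start + len - 1L, n)
    mapq <- ifelse(stats::runif(n_reads) < low_mapq_fraction,
                   sample.int(31L, n_reads, replace = TRUE) - 1L,
                   sample.int(30L, n_reads, replace = TRUE) + 30L)
    control <- data.frame(
      read_id = sprintf("read%06d", seq_len(n_reads)),
      transcript_id = s$transcript_id,
      start = start, end = as.integer(end), mapq = as.integer(mapq),
      stringsAsFactors = FALSE)
    loci <- sort(as.integer(cleavage_loci))
    if (!length(loci)) {
      treatment <- control
    } else if (model == "truncate") {
      treatment <- control
      for (r in seq_len(n_reads)) {
        spanned <- loci[loci > treatment$start[r] &
                        loci < treatment$end[r]]
        if (length(spanned) &&
            stats::runif(1L) < cleavage_efficiency) {
          treatment$end[r] <- spanned[1L]
        }
      }
    } else {
      rows <- vector("list", n_reads)
      for (r in seq_len(n_reads)) {
        spanned <- loci[loci > control$start[r] & loci < control$end[r]]
        cuts <- spanned[stats::runif(length(spanned)) <
                          cleavage_efficiency]
        if (!length(cuts)) {
          rows[[r]] <- control[r, , drop = FALSE]
        } else {
          # excise each cut nucleotide; keep fragments >= min_fragment
          fs <- c(control$start[r], cuts + 1L)
          fe <- c(cuts - 1L, control$end[r])
          keep <- fe - fs + 1L >= min_fragment
          if (any(keep))
            rows[[r]] <- data.frame(
              read_id = sprintf("%s/%d", control$read_id[r],
                                seq_len(sum(keep))),
              transcript_id = control$transcript_id[r],
              start = fs[keep], end = fe[keep],
              mapq = control$mapq[r], stringsAsFactors = FALSE)
        }
      }
      treatment <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
      rownames(treatment) <- NULL
    }
    structure(list(
      treatment = treatment, control = control,
      manifest = list(
        transcript_id = s$transcript_id, transcript_length = n,
        cleavage_loci = loci,
        n_reads = as.integer(n_reads),
        cleavage_efficiency = cleavage_efficiency, model = model,
        read_length_meanlog = read_length_meanlog,
        read_length_sdlog = read_length_sdlog,
        min_read_length = as.integer(min_len),
        low_mapq_fraction = low_mapq_fraction, seed = as.integer(seed))),
      class = "synthetic_experiment")
  })
}

#' Generate a complete synthetic experiment bundle
#'
#' Convenience wrapper tying the generators together: a structured
#' transcript, its probing track, and treatment/control read sets with
#' cleavage planted at the centres of the designed loops (SS regions),
#' mirroring the preference of Cas13 for single-stranded sites. The
#' default design is a 2-kb multi-stem transcript (four 300-nt loops on
#' 100-bp stems) -- large relative to the ~150-nt reads, so the coverage
#' deficit of a cut stays mostly within its loop under the default
#' truncation model. The returned manifest describes every planted
#' feature.
#'
#' @param design Stem/loop token design
#'   (see [make_structured_transcript()]).
#' @param seed Master seed; sub-generators derive distinct streams.
#' @param n_reads Reads per sample.
#' @param cleavage_efficiency Probability a loop-spanning read is cut.
#' @param noise_sd,masked_fraction Probing-track noise parameters.
#' @param ... Further arguments for [simulate_reads()] (e.g. `model`).
#' @return List of class `synthetic_bundle`: `structure`, `probing`,
#'   `reads` (a `synthetic_experiment`), `manifest`.
#' @export
synthetic_experiment <- function(design = c("s100", "l300", "e",
                                            "s100", "l300", "e",
                                            "s100", "l300", "e",
                                            "s100", "l300"),
                                 seed = 1L, n_reads = 10000L,
                                 cleavage_efficiency = 0.9,
                                 noise_sd = 0.5, masked_fraction = 0.05,
                                 ...) {
  s <- make_structured_transcript(design, seed = seed)
  state <- state_from_structure(s)
  seg <- segment_regions(state)
  ss <- seg$regions[seg$regions$cls == "SS", , drop = FALSE]
  # plant one cut at the centre of each SS region long enough to hold it
  ss <- ss[ss$end - ss$start + 1L >= 10L, , drop = FALSE]
  loci <- as.integer((ss$start + ss$end) %/% 2L)
  probing <- simulate_probing(s, noise_sd = noise_sd,
                              masked_fraction = masked_fraction,
                              seed = seed + 1L)
  reads <- simulate_reads(s, cleavage_loci = loci, n_reads = n_reads,
                          cleavage_efficiency = cleavage_efficiency,
                          seed = seed + 2L, ...)
  structure(list(
    structure = s, probing = probing, reads = reads,
    manifest = c(list(design = design, seed = as.integer(seed),
                      noise_sd = noise_sd,
                      masked_fraction = masked_fraction,
                      regions = seg$regions),
                 reads$manifest)),
    class = "synthetic_bundle")
}
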