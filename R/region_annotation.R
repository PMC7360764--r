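## Per-nucleotide strand-state calling (from pairing state or probing
## scores), segmentation into maximal SS/DS regions with junctions, and
## pseudoknot (crossing base pair) annotation.

#' Per-position strand state from a secondary structure
#'
#' A position is double-stranded (DS) iff it has a pairing partner, else
#' single-stranded (SS). Structure-derived states are never `unknown`.
#'
#' @param s A [transcript_structure].
#' @return Character vector over `c("SS","DS")`, one entry per position.
#' @export
state_from_structure <- function(s) {
  ifelse(s$pair > 0L, "DS", "SS")
}

#' Per-position strand state from a probing score track
#'
#' PARS convention: scores above `threshold + dead_zone` are called DS,
#' below `threshold - dead_zone` SS. Scores inside the dead zone --
#' including a score exactly at the threshold -- and masked positions are
#' `unknown`; downstream scoring never counts unknown positions as SS.
#'
#' @param track A `probing_track`.
#' @param threshold Score midpoint separating SS from DS calls.
#' @param dead_zone Half-width of the no-call band around the threshold
#'   (same units as the score); must be `>= 0`.
#' @return Character vector over `c("SS","DS","unknown")`.
#' @export
state_from_probing <- function(track, threshold = 0, dead_zone = 0) {
  stopifnot(dead_zone >= 0)
  sc <- track$scores
  out <- rep("unknown", length(sc))
  out[!is.na(sc) & sc > threshold + dead_zone] <- "DS"
  out[!is.na(sc) & sc < threshold - dead_zone] <- "SS"
  out
}

#' Segment a strand-state vector into maximal regions and junctions
#'
#' Regions are maximal runs of identical non-unknown calls (adjacent
#' regions always differ in class, runs of length 1 are kept). A junction
#' is emitted at every boundary where an SS region directly abuts a DS
#' region; a gap of unknown positions between two regions is not a
#' junction.
#'
#' @param state Character vector over `c("SS","DS","unknown")`.
#' @return List with `regions` (`data.frame`: `start`, `end`, `cls`; 1-based
#'   inclusive) and `junctions` (`data.frame`: `boundary` = last position of
#'   the left region, `left`, `right` classes).
#' @export
segment_regions <- function(state) {
  r <- rle(state)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  keep <- r$values != "unknown"
  regions <- data.frame(start = start[keep], end = end[keep],
                        cls = r$values[keep],
                        stringsAsFactors = FALSE)
  junctions <- data.frame(boundary = integer(0), left = character(0),
                          right = character(0), stringsAsFactors = FALSE)
  if (nrow(regions) > 1L) {
    adj <- which(regions$end[-nrow(regions)] + 1L == regions$start[-1L] &
                 regions$cls[-nrow(regions)] != regions$cls[-1L])
    if (length(adj))
      junctions <- data.frame(boundary = regions$end[adj],
                              left = regions$cls[adj],
                              right = regions$cls[adj + 1L],
                              stringsAsFactors = FALSE)
  }
  list(regions = regions, junctions = junctions)
}

#' Median-filter smoothing of a strand-state vector
#'
#' Optional majority smoothing before segmentation; off by default
#' throughout the package. Within a centred window of odd width, the
#' position is re-called to the majority non-unknown class (ties and
#' all-unknown windows leave the original call).
#'
#' @param state Character state vector.
#' @param window Odd window width; `1` is a no-op.
#' @export
smooth_state <- function(state, window = 1L) {
  window <- as.integer(window)
  stopifnot(window >= 1L, window %% 2L == 1L)
  if (window == 1L) return(state)
  n <- length(state)
  h <- window %/% 2L
  out <- state
  for (i in seq_len(n)) {
    w <- state[max(1L, i - h):min(n, i + h)]
    n_ss <- sum(w == "SS"); n_ds <- sum(w == "DS")
    if (n_ss > n_ds) out[i] <- "SS"
    else if (n_ds > n_ss) out[i] <- "DS"
  }
  out
}

#' Detect pseudoknots as crossing base pairs
#'
#' Two pairs (i,j) and (k,l), written with i<j and k<l, cross iff
#' i < k < j < l (or symmetrically k < i < l < j). Every pair involved in
#' at least one crossing relation is reported; no attempt is made to
#' decide which side of a crossing is "the knot" -- participation is
#' symmetric, matching per-base pseudoknot counting.
#'
#' @param s A [transcript_structure].
#' @return List of class `pseudoknot_annotation` with `crossing_pairs`
#'   (`data.frame` `i`,`j`, subset of [structure_pairs()]) and
#'   `is_knot_base` (logical per position).
#' @export
detect_pseudoknots <- function(s) {
  pairs <- structure_pairs(s)
  n <- length(s)
  crossing <- logical(nrow(pairs))
  if (nrow(pairs) > 1L) {
    for (a in seq_len(nrow(pairs) - 1L)) {
      for (b in (a + 1L):nrow(pairs)) {
        i <- pairs$i[a]; j <- pairs$j[a]
        k <- pairs$i[b]; l <- pairs$j[b]
        if ((i < k & k < j & j < l) || (k < i & i < l & l < j)) {
          crossing[a] <- TRUE
          crossing[b] <- TRUE
        }
      }
    }
  }
  cp <- pairs[crossing, , drop = FALSE]
  rownames(cp) <- NULL
  is_knot <- logical(n)
  is_knot[c(cp$i, cp$j)] <- TRUE
  structure(list(crossing_pairs = cp, is_knot_base = is_knot),
            class = "pseudoknot_annotation")
}

#' @export
print.pseudoknot_annotation <- function(x, ...) {
  cat("pseudoknot_annotation: ", nrow(x$crossing_pairs),
      " crossing pair(s), ", sum(x$is_knot_base),
      " participating base(s)\n", sep = "")
  invisible(x)
}

#' Count pseudoknot-participating bases in a window
#'
#' @param annotation A `pseudoknot_annotation`.
#' @param start,end 1-based inclusive window on the transcript.
#' @return Number of positions in `[start, end]` that belong to a crossing
#'   pair.
#' @export
knot_bases_in_window <- function(annotation, start, end) {
  n <- length(annotation$is_knot_base)
  if (start < 1L || end > n || start > end)
    stop("window [", start, ",", end, "] outside transcript 1..", n)
  sum(annotation$is_knot_base[start:end])
}

#' Export SS/DS regions (and optionally pseudoknot loci) as BED
#'
#' BED is 0-based half-open; internal coordinates are 1-based inclusive,
#' so a region `(start, end)` becomes `start-1, end`. The name field
#' carries the class, the score field is 0.
#'
#' @param regions Region `data.frame` from [segment_regions()].
#' @param transcript_id Seqname for the BED rows.
#' @param file Path, or `NULL` to return the lines.
#' @param knots Optional `pseudoknot_annotation`; contiguous runs of knot
#'   bases are appended as `knot` rows.
#' @export
export_regions_bed <- function(regions, transcript_id, file = NULL,
                               knots = NULL) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t+", transcript_id,
                   regions$start - 1L, regions$end, regions$cls)
  if (!is.null(knots) && any(knots$is_knot_base)) {
    r <- rle(knots$is_knot_base)
    end <- cumsum(r$lengths); start <- end - r$lengths + 1L
    ki <- which(r$values)
    lines <- c(lines, sprintf("%s\t%d\t%d\tknot\t0\t+", transcript_id,
                              start[ki] - 1L, end[ki]))
  }
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(file)
}

#' Read a BED file of SS/DS regions back to 1-based regions
#'
#' @param file BED path (first four columns used).
#' @return `data.frame` with `transcript_id`, `start`, `end` (1-based
#'   inclusive), `cls`.
#' @export
read_regions_bed <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("BED needs at least 4 columns (name = class)")
  data.frame(transcript_id = df[[1L]], start = df[[2L]] + 1L,
             end = df[[3L]], cls = df[[4L]], stringsAsFactors = FALSE)
}

#' Export junctions as TSV
#' @param junctions Junction `data.frame` from [segment_regions()].
#' @param transcript_id Transcript id column value.
#' @param file Path, or `NULL` for lines.
#' @export
export_junctions_tsv <- function(junctions, transcript_id, file = NULL) {
  lines <- c("transcript_id\tboundary\tleft\tright",
             sprintf("%s\t%d\t%s\t%s", transcript_id, junctions$boundary,
                     junctions$left, junctions$right))
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(file)
}
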