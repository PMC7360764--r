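## Cleavage quantification from treatment-versus-control alignments:
## MAPQ filtering, per-position coverage, a coverage-drop cleavage call,
## the region-level cleavage-rate statistic
## (cleaved nucleotides / total nucleotides x 100), and a rank-sum
## comparison of SS versus DS region rates.

#' Read alignments from a simplified TSV
#'
#' Columns: `read_id`, `transcript_id`, `start`, `end` (1-based inclusive
#' on the transcript), `mapq` (Phred-scaled). A header line is detected
#' and skipped.
#'
#' @param file Path or character lines.
#' @return `data.frame` of alignments.
#' @export
read_alignments_tsv <- function(file) {
  lines <- .as_lines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^read_id\t", lines[1L]))
    lines <- lines[-1L]
  if (!length(lines))
    return(data.frame(read_id = character(0), transcript_id = character(0),
                      start = integer(0), end = integer(0),
                      mapq = integer(0), stringsAsFactors = FALSE))
  df <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                          col.names = c("read_id", "transcript_id",
                                        "start", "end", "mapq"),
                          stringsAsFactors = FALSE)
  validate_alignments(df)
  df
}

#' Read alignments from a SAM file
#'
#' Uses Rsamtools/GenomicAlignments: the SAM is converted to BAM
#' internally, reference-space read extents are derived from the CIGAR,
#' and unmapped records are dropped.
#'
#' @param file SAM path (must carry `@SQ` header lines).
#' @return `data.frame` with `read_id`, `transcript_id`, `start`, `end`,
#'   `mapq`.
#' @export
read_alignments_sam <- function(file) {
  bam <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "mapq"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))
  df <- data.frame(
    read_id = S4Vectors::mcols(ga)$qname,
    transcript_id = as.character(GenomeInfoDb::seqnames(ga)),
    start = BiocGenerics::start(ga),
    end = BiocGenerics::end(ga),
    mapq = S4Vectors::mcols(ga)$mapq,
    stringsAsFactors = FALSE)
  validate_alignments(df)
  df
}

validate_alignments <- function(df) {
  stopifnot(all(c("read_id", "transcript_id", "start", "end", "mapq")
                %in% names(df)))
  if (any(df$start > df$end)) stop("alignment with start > end")
  if (any(df$start < 1L)) stop("alignment start < 1")
  if (any(df$mapq < 0L)) stop("negative MAPQ")
  invisible(df)
}

#' Write alignments as the simplified TSV
#' @param reads Alignment `data.frame`.
#' @param file Path.
#' @export
write_alignments_tsv <- function(reads, file) {
  utils::write.table(reads, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(file)
}

#' Write alignments as SAM
#' @param reads Alignment `data.frame`.
#' @param transcript_length Length for the `@SQ` header.
#' @param file Path.
#' @export
write_alignments_sam <- function(reads, transcript_length, file) {
  tid <- unique(reads$transcript_id)
  stopifnot(length(tid) == 1L)
  lens <- reads$end - reads$start + 1L
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", tid, transcript_length),
    sprintf("%s\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
            reads$read_id, reads$transcript_id, reads$start, reads$mapq,
            lens, strrep("A", lens)))
  writeLines(lines, file)
  invisible(file)
}

#' Filter alignments on mapping quality
#'
#' Retains exactly the reads with MAPQ strictly greater than `mapq_min`;
#' the default 30 corresponds to less than 5% probability that the read
#' is wrongly mapped (sic: the conventional Phred gloss for Q30 is 0.1%).
#' Idempotent; the retained set shrinks as `mapq_min` grows.
#'
#' @param reads Alignment `data.frame`.
#' @param mapq_min Threshold; reads with `mapq > mapq_min` are kept.
#' @export
filter_alignments <- function(reads, mapq_min = 30L) {
  stopifnot(mapq_min >= 0L)
  out <- reads[reads$mapq > mapq_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-position coverage profile of one transcript
#'
#' Depth at position i is the number of reads whose interval contains i
#' (computed with IRanges coverage). The normalised view scales depth by
#' 1e6 / retained-read count (counts per million reads).
#'
#' @param reads Alignment `data.frame` for a single transcript.
#' @param transcript_length Transcript length.
#' @return List of class `coverage_profile`: `depth` (integer vector),
#'   `norm_depth` (CPM-scaled), `n_reads`.
#' @export
coverage_profile <- function(reads, transcript_length) {
  transcript_length <- as.integer(transcript_length)
  if (nrow(reads)) {
    if (length(unique(reads$transcript_id)) > 1L)
      stop("coverage_profile expects reads on one transcript")
    if (any(reads$end > transcript_length))
      stop("read interval beyond transcript end (",
           max(reads$end), " > ", transcript_length, ")")
    cov <- IRanges::coverage(
      IRanges::IRanges(start = reads$start, end = reads$end),
      width = transcript_length)
    depth <- as.integer(cov)
  } else {
    depth <- integer(transcript_length)
  }
  n <- nrow(reads)
  structure(list(depth = depth,
                 norm_depth = if (n > 0L) depth * (1e6 / n) else
                   as.numeric(depth),
                 n_reads = n),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("coverage_profile: ", length(x$depth), " nt, ", x$n_reads,
      " reads, mean depth ", round(mean(x$depth), 2), "\n", sep = "")
  invisible(x)
}

#' Call cleaved nucleotides by coverage drop
#'
#' Position i is called cleaved when the control has enough evidence
#' (normalised depth at least `min_control_depth`) and the treatment's
#' normalised depth has fallen to at most `drop_fraction` times the
#' control's. Normalised (CPM) depths are compared so library sizes
#' cancel.
#'
#' @param treatment,control `coverage_profile`s of equal length.
#' @param drop_fraction Maximal retained fraction of control coverage for
#'   a cleaved call, in (0, 1].
#' @param min_control_depth Minimum control normalised depth for a
#'   position to be callable.
#' @return Logical vector, `TRUE` = cleaved.
#' @export
call_cleavage <- function(treatment, control, drop_fraction = 0.5,
                          min_control_depth = 10) {
  stopifnot(drop_fraction > 0, drop_fraction <= 1)
  if (length(treatment$depth) != length(control$depth))
    stop("treatment and control profiles differ in length")
  ctrl <- control$norm_depth
  trt <- treatment$norm_depth
  ctrl >= min_control_depth & trt <= drop_fraction * ctrl
}

#' Region cleavage rate
#'
#' The region-level statistic: cleaved nucleotides in the region divided
#' by total nucleotides in the region, times 100.
#'
#' @param start,end Region span, 1-based inclusive.
#' @param cleaved Logical per-position cleavage calls.
#' @return Percentage in \[0, 100\].
#' @export
cleavage_rate <- function(start, end, cleaved) {
  n <- length(cleaved)
  if (start < 1L || end > n || start > end)
    stop("region [", start, ",", end, "] invalid for transcript 1..", n)
  100 * sum(cleaved[start:end]) / (end - start + 1L)
}

#' Per-region cleavage report with SS-versus-DS comparison
#'
#' Applies [cleavage_rate()] to every annotated region, aggregates
#' numerators and denominators per class (the aggregate rate is the
#' length-weighted mean of member-region rates), and compares the SS and
#' DS per-region rate distributions with a two-tailed rank-sum test (see
#' [compare_ss_ds()]).
#'
#' @param regions Region `data.frame` (`start`, `end`, `cls`).
#' @param cleaved Logical per-position cleavage calls.
#' @return List of class `cleavage_report`: `per_region` table,
#'   `aggregate` table (per class), `comparison` (`statistic`, `p_value`,
#'   `stars`) or `NULL` when a class is absent.
#' @export
cleavage_report <- function(regions, cleaved) {
  if (!nrow(regions)) stop("empty region set")
  per <- regions
  per$total_nucleotides <- per$end - per$start + 1L
  per$cleaved_nucleotides <- vapply(seq_len(nrow(per)), function(r)
    sum(cleaved[per$start[r]:per$end[r]]), 0L)
  per$rate <- 100 * per$cleaved_nucleotides / per$total_nucleotides
  agg <- do.call(rbind, lapply(split(per, per$cls), function(d)
    data.frame(cls = d$cls[1L],
               cleaved_nucleotides = sum(d$cleaved_nucleotides),
               total_nucleotides = sum(d$total_nucleotides),
               rate = 100 * sum(d$cleaved_nucleotides) /
                 sum(d$total_nucleotides),
               n_regions = nrow(d), stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  comparison <- NULL
  if (all(c("SS", "DS") %in% per$cls)) {
    ss <- per$rate[per$cls == "SS"]
    ds <- per$rate[per$cls == "DS"]
    if (length(ss) >= 2L && length(ds) >= 2L)
      comparison <- compare_ss_ds(ss, ds)
  }
  structure(list(per_region = per, aggregate = agg,
                 comparison = comparison),
            class = "cleavage_report")
}

#' @export
print.cleavage_report <- function(x, ...) {
  cat("cleavage_report:", nrow(x$per_region), "regions\n")
  print(x$aggregate)
  if (!is.null(x$comparison))
    cat("SS vs DS rank-sum: W = ", x$comparison$statistic,
        ", p = ", signif(x$comparison$p_value, 3), " ",
        x$comparison$stars, "\n", sep = "")
  invisible(x)
}

#' Rank-sum comparison of SS and DS region cleavage rates
#'
#' Two-sample Wilcoxon rank-sum test on the per-region rates, two-tailed.
#' For small samples (total n <= `exact_max`) the null distribution of
#' the rank-sum statistic is enumerated exactly over all group
#' assignments, which remains valid under ties (midranks); larger samples
#' use the normal approximation with tie correction via
#' [stats::wilcox.test()].
#'
#' @param ss_rates,ds_rates Numeric per-region rate vectors, each length
#'   >= 2.
#' @param exact_max Largest total sample size for exact enumeration.
#' @return List `statistic` (rank-sum W of the SS group, midranks),
#'   `p_value`, `stars` (`***` p<0.001, `**` p<0.01, `*` p<0.05, `ns`).
#' @export
compare_ss_ds <- function(ss_rates, ds_rates, exact_max = 16L) {
  if (length(ss_rates) < 2L || length(ds_rates) < 2L)
    stop("need at least 2 regions per class for the rank-sum comparison")
  n1 <- length(ss_rates); n2 <- length(ds_rates)
  pooled <- c(ss_rates, ds_rates)
  rk <- rank(pooled)
  w_obs <- sum(rk[seq_len(n1)])
  if (n1 + n2 <= exact_max) {
    combs <- utils::combn(n1 + n2, n1)
    w_all <- apply(combs, 2L, function(idx) sum(rk[idx]))
    center <- n1 * (n1 + n2 + 1) / 2
    p <- mean(abs(w_all - center) >= abs(w_obs - center) - 1e-9)
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(ss_rates, ds_rates, exact = FALSE,
                         correct = TRUE))
    p <- wt$p.value
  }
  list(statistic = w_obs, p_value = p, stars = significance_stars(p))
}

#' Significance stars for a p-value
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `ns` otherwise.
#' @param p P-value.
#' @export
significance_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

#' Log2 fold expression relative to an internal control gene
#'
#' Expression of the target normalised to the control gene, then to the
#' reference condition: `log2((target/control) / (ref_target/ref_control))`.
#'
#' @param target_counts Target-gene quantification per condition.
#' @param control_gene_counts Internal-control quantification per
#'   condition (all positive).
#' @param reference Index of the reference condition (default 1).
#' @return Numeric log2 fold values, 0 at the reference condition.
#' @export
log2_fold_expression <- function(target_counts, control_gene_counts,
                                 reference = 1L) {
  stopifnot(length(target_counts) == length(control_gene_counts))
  if (any(control_gene_counts <= 0))
    stop("control gene counts must be positive")
  ratio <- target_counts / control_gene_counts
  log2(ratio / ratio[reference])
}

#' Export per-position cleavage calls as BED
#'
#' Contiguous cleaved runs become BED rows (0-based half-open), named
#' `cleaved`.
#' @param cleaved Logical calls.
#' @param transcript_id Seqname.
#' @param file Path, or `NULL` for lines.
#' @export
export_cleavage_bed <- function(cleaved, transcript_id, file = NULL) {
  lines <- character(0)
  if (any(cleaved)) {
    r <- rle(cleaved)
    end <- cumsum(r$lengths); start <- end - r$lengths + 1L
    ki <- which(r$values)
    lines <- sprintf("%s\t%d\t%d\tcleaved\t0\t+", transcript_id,
                     start[ki] - 1L, end[ki])
  }
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(file)
}
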