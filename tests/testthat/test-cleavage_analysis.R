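make_reads <- function(start, end, mapq = 60L, id = NULL) {
  data.frame(read_id = id %||% sprintf("r%d", seq_along(start)),
             transcript_id = "tx", start = start, end = end,
             mapq = rep_len(mapq, length(start)),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("MAPQ filter keeps strictly greater than the threshold", {
  reads <- make_reads(c(1, 1, 1, 1), c(10, 10, 10, 10),
                      mapq = c(0L, 30L, 31L, 60L))
  kept <- filter_alignments(reads)
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$mapq, c(31L, 60L))
  # boundary at 0 and idempotence
  expect_equal(filter_alignments(reads, 0L)$mapq, c(30L, 31L, 60L))
  expect_identical(filter_alignments(kept), kept)
  expect_equal(nrow(filter_alignments(reads[0, , drop = FALSE])), 0L)
  # retained set shrinks monotonically in the threshold
  prev <- nrow(reads)
  for (q in c(0, 10, 30, 50, 70)) {
    cur <- nrow(filter_alignments(reads, q))
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("coverage equals per-position read membership", {
  p <- coverage_profile(make_reads(1, 10), 20)
  expect_equal(p$depth, c(rep(1L, 10), rep(0L, 10)))
  p2 <- coverage_profile(make_reads(c(1, 5), c(10, 15)), 20)
  expect_equal(p2$depth[5:10], rep(2L, 6))
  expect_error(coverage_profile(make_reads(1, 25), 20), "beyond")
  set.seed(23)
  for (k in 1:15) {
    n <- sample(50:200, 1)
    m <- sample(1:60, 1)
    st <- sample(n, m, replace = TRUE)
    en <- pmin(st + sample(1:50, m, replace = TRUE), n)
    reads <- make_reads(st, en)
    p <- coverage_profile(reads, n)
    expect_equal(p$depth, oracle_coverage(reads, n))
    expect_equal(p$norm_depth, p$depth * 1e6 / m)
  }
})

test_that("cleavage calls require control evidence and a coverage drop", {
  ctl <- structure(list(depth = c(100L, 100L, 2L),
                        norm_depth = c(100, 100, 2), n_reads = 100L),
                   class = "coverage_profile")
  trt <- structure(list(depth = c(10L, 80L, 0L),
                        norm_depth = c(10, 80, 0), n_reads = 100L),
                   class = "coverage_profile")
  cl <- call_cleavage(trt, ctl, drop_fraction = 0.5,
                      min_control_depth = 5)
  expect_equal(cl, c(TRUE, FALSE, FALSE))  # 3rd: too little control
  expect_error(call_cleavage(trt, structure(
    list(depth = 1L, norm_depth = 1, n_reads = 1L),
    class = "coverage_profile")), "length")
})

test_that("planted excision dips are recovered exactly (+/- 1)", {
  # excision-style fixture: uniform control, treatment dips at loci
  n <- 400L
  loci <- c(80L, 200L, 311L)
  depth_c <- rep(50L, n)
  depth_t <- rep(50L, n)
  depth_t[loci] <- 4L
  ctl <- structure(list(depth = depth_c, norm_depth = depth_c * 1e6 / 5e4,
                        n_reads = 50000L), class = "coverage_profile")
  trt <- structure(list(depth = depth_t, norm_depth = depth_t * 1e6 / 5e4,
                        n_reads = 50000L), class = "coverage_profile")
  called <- which(call_cleavage(trt, ctl))
  expect_true(all(vapply(called, function(x)
    min(abs(x - loci)) <= 1L, TRUE)))
  expect_true(all(loci %in% called))
})

test_that("fragment-model simulation recovers planted loci exactly", {
  s <- make_structured_transcript(
    c("s100", "l300", "e", "s100", "l300"), seed = 4)
  loci <- c(250L, 750L)
  sim <- simulate_reads(s, loci, n_reads = 8000L,
                        cleavage_efficiency = 0.95,
                        model = "fragment", seed = 5)
  trt <- coverage_profile(filter_alignments(sim$treatment), length(s))
  ctl <- coverage_profile(filter_alignments(sim$control), length(s))
  called <- which(call_cleavage(trt, ctl))
  expect_true(all(vapply(called, function(x)
    min(abs(x - loci)) <= 1L, TRUE)))
  expect_true(all(vapply(loci, function(x)
    min(abs(x - called)) <= 1L, TRUE)))
})

test_that("cleavage rate is the printed percentage formula", {
  cl <- c(rep(TRUE, 10), rep(FALSE, 40))
  expect_equal(cleavage_rate(1, 50, cl), 20.0)
  expect_equal(cleavage_rate(11, 50, cl), 0.0)
  expect_equal(cleavage_rate(1, 10, cl), 100.0)
  expect_error(cleavage_rate(0, 10, cl), "invalid")
})

test_that("report aggregates are length-weighted sums over regions", {
  regions <- data.frame(start = c(1, 11, 31, 61),
                        end = c(10, 30, 60, 100),
                        cls = c("SS", "DS", "SS", "DS"))
  cl <- rep(FALSE, 100)
  cl[1:5] <- TRUE      # SS region 1: 5/10
  cl[31:42] <- TRUE    # SS region 2: 12/30
  cl[15] <- TRUE       # DS region 1: 1/20
  rep_ <- cleavage_report(regions, cl)
  per <- rep_$per_region
  expect_equal(per$cleaved_nucleotides, c(5L, 1L, 12L, 0L))
  expect_equal(per$rate, c(50, 5, 40, 0))
  agg <- rep_$aggregate
  ss <- agg[agg$cls == "SS", ]
  expect_equal(ss$cleaved_nucleotides, 17L)
  expect_equal(ss$total_nucleotides, 40L)
  expect_equal(ss$rate, 100 * 17 / 40)
  # aggregate rate equals the length-weighted mean of member rates
  w <- per$total_nucleotides[per$cls == "SS"]
  expect_equal(ss$rate, sum(per$rate[per$cls == "SS"] * w) / sum(w))
  expect_true(all(per$rate >= 0 & per$rate <= 100))
  expect_error(cleavage_report(regions[0, ], cl), "empty")
})

test_that("rank-sum comparison: null, maximal separation and exactness", {
  same <- compare_ss_ds(c(10, 20, 30, 40), c(10, 20, 30, 40))
  expect_gt(same$p_value, 0.05)
  expect_equal(same$stars, "ns")

  sep <- compare_ss_ds(rep(100, 4), rep(0, 4))
  # smallest achievable two-tailed p for 4 vs 4: 2 / choose(8,4)
  expect_equal(sep$p_value, 2 / choose(8, 4))
  expect_equal(sep$stars, "*")

  expect_error(compare_ss_ds(c(1), c(1, 2, 3)), "at least 2")

  # exact enumeration agrees with wilcox.test on tie-free data
  set.seed(29)
  for (k in 1:10) {
    a <- rnorm(sample(3:6, 1))
    b <- rnorm(sample(3:6, 1)) + rnorm(1)
    got <- compare_ss_ds(a, b)
    want <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(got$p_value, want$p.value, tolerance = 1e-10)
  }
  # large-sample path returns a valid p
  big <- compare_ss_ds(rnorm(12) + 2, rnorm(12))
  expect_lt(big$p_value, 0.05)
})

test_that("significance stars follow the 0.05/0.01/0.001 convention", {
  expect_equal(significance_stars(0.0005), "***")
  expect_equal(significance_stars(0.005), "**")
  expect_equal(significance_stars(0.049), "*")
  expect_equal(significance_stars(0.07), "ns")
})

test_that("log2 fold expression is relative to the control gene", {
  expect_equal(log2_fold_expression(c(100, 50), c(10, 10)), c(0, -1))
  expect_equal(log2_fold_expression(c(100, 100), c(10, 10)), c(0, 0))
  expect_equal(log2_fold_expression(c(100, 20), c(10, 10))[2],
               log2(1 / 5))
  # control-gene drift cancels
  expect_equal(log2_fold_expression(c(100, 50), c(10, 5)), c(0, 0))
  expect_error(log2_fold_expression(c(1, 1), c(0, 1)), "positive")
})

test_that("SAM round trip preserves intervals and mapping quality", {
  reads <- make_reads(c(1L, 40L, 90L), c(30L, 80L, 120L),
                      mapq = c(10L, 35L, 60L))
  f <- tempfile(fileext = ".sam")
  write_alignments_sam(reads, 150L, f)
  back <- read_alignments_sam(f)
  back <- back[order(back$start), ]
  expect_equal(back$start, reads$start)
  expect_equal(back$end, reads$end)
  expect_equal(back$mapq, reads$mapq)
  expect_equal(unique(back$transcript_id), "tx")

  f2 <- tempfile(fileext = ".tsv")
  write_alignments_tsv(reads, f2)
  back2 <- read_alignments_tsv(f2)
  expect_equal(back2, reads)
})
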