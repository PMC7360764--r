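test_that("central seed window is the centred 8-mer", {
  expect_equal(unname(central_seed_window(28)), c(11, 18))
  expect_equal(unname(central_seed_window(20)), c(7, 14))
  expect_equal(unname(central_seed_window(8)), c(1, 8))
  expect_equal(diff(unname(central_seed_window(23))) + 1, 8)
  expect_error(central_seed_window(7), "central seed")
})

test_that("spacer lengths outside 20-28 are rejected", {
  expect_error(validate_spacer_length(19), "20-28")
  expect_error(validate_spacer_length(29), "20-28")
  expect_equal(validate_spacer_length(20), 20L)
  expect_equal(validate_spacer_length(28), 28L)
  expect_error(design_config(spacer_length = 30))
})

test_that("SS-overlap scores equal a per-position tally at any offset", {
  # fully SS and fully DS windows
  state <- c(rep("SS", 30), rep("DS", 30))
  sc <- score_ss_overlap(1, 28, state)
  expect_equal(sc$ss_complement_count, 28)
  expect_equal(sc$central_seed_ss_count, 8)
  sc2 <- score_ss_overlap(31, 58, state)
  expect_equal(sc2$ss_complement_count, 0)
  expect_equal(sc2$central_seed_ss_count, 0)

  # straddling the junction at every offset: brute-force positional tally
  seed <- central_seed_window(28)
  for (start in 5:32) {
    end <- start + 27
    sc <- score_ss_overlap(start, end, state)
    expect_equal(sc$ss_complement_count, sum(state[start:end] == "SS"))
    seed_tx <- (end - seed[2] + 1):(end - seed[1] + 1)
    expect_equal(sc$central_seed_ss_count, sum(state[seed_tx] == "SS"))
  }
  # unknown positions count as not-SS and are reported separately
  state[10] <- "unknown"
  sc3 <- score_ss_overlap(1, 28, state)
  expect_equal(sc3$ss_complement_count, 27)
  expect_equal(sc3$unknown_count, 1)
})

test_that("efficiency classes follow the seed and total-count rules", {
  cfg <- design_config()
  expect_equal(classify_efficiency(10, 5, cfg), "poor")
  expect_equal(classify_efficiency(12, 8, cfg), "efficient")
  expect_equal(classify_efficiency(19, 6, cfg), "efficient")
  expect_equal(classify_efficiency(0, 0, cfg), "poor")
  expect_equal(classify_efficiency(11, 7, cfg), "intermediate")
  expect_equal(classify_efficiency(17, 7, cfg), "intermediate")
  expect_equal(classify_efficiency(18, 0, cfg), "efficient")
})

test_that("classification is monotone in the SS count and seed rule", {
  cfg <- design_config()
  rank <- c(poor = 1, intermediate = 2, efficient = 3)
  for (seed_ss in 0:7) {
    prev <- 0
    for (ss in seed_ss:28) {
      cur <- rank[[classify_efficiency(ss, seed_ss, cfg)]]
      expect_gte(cur, prev)
      prev <- cur
    }
  }
  for (ss in 8:28)
    expect_equal(classify_efficiency(ss, 8, cfg), "efficient")
})

test_that("PFS annotation reports flanks, edges and the 3' G soft flag", {
  seq <- paste0("A", strrep("C", 28), "G")  # 30 nt
  pfs <- extract_pfs(seq, 2, 29)
  expect_equal(pfs$pfs_5prime, "A")
  expect_equal(pfs$pfs_3prime, "G")
  expect_true(pfs$pfs_flag)
  edge <- extract_pfs(seq, 3, 30)
  expect_equal(edge$pfs_3prime, "N")
  expect_false(edge$pfs_flag)
  expect_equal(extract_pfs(seq, 1, 28)$pfs_5prime, "N")
  none <- extract_pfs(seq, 2, 29, design_config(pfs_profile = "none"))
  expect_false(none$pfs_flag)
})

test_that("sequence filters agree with exhaustive scans", {
  cfg <- design_config()
  # 5-bp stem, 4-nt loop hairpin
  hair <- "GGGGGCAAAGCCCCCAAAAUUUCCGGAU"
  expect_true("self_complementary" %in% sequence_filters(hair, cfg))
  expect_true(oracle_has_hairpin(hair, 5, 3))
  # homopolymer
  expect_true("low_complexity" %in%
              sequence_filters(paste0("AAAAAA", random_rna(22)), cfg))
  # random high-entropy spacers: flags match the oracle
  set.seed(13)
  n_clean <- 0
  for (k in 1:30) {
    sp <- random_rna(28)
    flags <- sequence_filters(sp, cfg)
    expect_equal("self_complementary" %in% flags,
                 oracle_has_hairpin(sp, 5, 3))
    if (!length(flags)) n_clean <- n_clean + 1
  }
  expect_gt(n_clean, 0)
})

test_that("self-dimer run length detects designed palindromes", {
  # a spacer beginning with an 8-nt self reverse-complementary block
  sp <- paste0("GGGGCCCC", "AUAUCAGUCAGUCGAUCCAG")
  expect_gte(longest_selfdimer_run(sp), 8)
  expect_true("dimer_prone" %in% sequence_filters(sp))
})

test_that("off-target scan equals a naive mismatch scan", {
  proto <- random_rna(28)
  bg <- c(target = paste0(random_rna(20), proto, random_rna(20)))
  hits <- off_target_scan(proto, bg, 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 21L)
  expect_equal(hits$mismatches, 0L)

  # planted single substitution found at max_mismatches 1, not 0
  mut <- proto
  substr(mut, 14, 14) <- setdiff(c("A", "C", "G", "U"),
                                 substr(proto, 14, 14))[1]
  bg2 <- c(decoy = paste0(random_rna(10), mut, random_rna(10)))
  expect_equal(nrow(off_target_scan(proto, bg2, 0)), 0L)
  expect_equal(nrow(off_target_scan(proto, bg2, 1)), 1L)

  set.seed(17)
  for (k in 1:10) {
    p <- random_rna(15)
    subj <- random_rna(300)
    got <- off_target_scan(p, c(s = subj), 2)
    want_fwd <- oracle_mismatch_hits(p, subj, 2)
    want_rev <- oracle_mismatch_hits(rna_reverse_complement(p), subj, 2)
    expect_equal(sort(got$start[got$strand == "+"]), want_fwd)
    expect_equal(sort(got$start[got$strand == "-"]), want_rev)
  }
})

test_that("cloning oligos carry the BbsI adapter and strip back", {
  cfg <- design_config()
  sp <- random_rna(28)
  ol <- render_cloning_oligos(sp, cfg)
  expect_equal(nchar(ol$forward), 28 + nchar(cfg$adapter_fwd))
  expect_true(grepl("GAAGAC", ol$forward))
  expect_true(grepl("GAAGAC", ol$reverse))
  stripped <- substring(ol$forward, nchar(cfg$adapter_fwd) + 1)
  expect_equal(stripped, chartr("U", "T", sp))
  rc <- substring(ol$reverse, nchar(cfg$adapter_rev) + 1)
  expect_equal(rc, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", sp)))))
})

test_that("candidate enumeration covers every window and ranks stably", {
  expect_error(
    enumerate_candidates(random_rna(12), rep("SS", 12), design_config()),
    "shorter")
  set.seed(19)
  seq50 <- random_rna(50)
  cand <- enumerate_candidates(seq50, rep("SS", 50), design_config())
  expect_equal(nrow(cand), 23L)  # 50 - 28 + 1
  expect_equal(sort(cand$protospacer_start), 1:23)
  # ties broken by start ascending; rerun identical
  cand2 <- enumerate_candidates(seq50, rep("SS", 50), design_config())
  expect_identical(cand, cand2)
  expect_false(is.unsorted(cand$protospacer_start[
    cand$central_seed_ss_count == 8 & cand$ss_complement_count == 28]))
  # spacer is the exact reverse complement of the protospacer
  for (r in c(1, 10, 23)) {
    proto <- substr(seq50, cand$protospacer_start[r],
                    cand$protospacer_end[r])
    expect_equal(cand$spacer_sequence[r], rna_reverse_complement(proto))
  }
})

test_that("top-ranked guide on a hairpin transcript sits in the loop", {
  s <- make_structured_transcript(c("s30", "l60"), seed = 2)
  state <- state_from_structure(s)
  cand <- enumerate_candidates(s$sequence, state)
  top <- cand[1, ]
  expect_equal(top$efficiency_class, "efficient")
  seed_tx <- (top$protospacer_end - top$central_seed_end + 1):
    (top$protospacer_end - top$central_seed_start + 1)
  expect_true(all(seed_tx >= 31 & seed_tx <= 90))  # designed loop
  expect_true(all(state[seed_tx] == "SS"))
})

test_that("junction coverage flags guides spanning an SS/DS boundary", {
  state <- c(rep("DS", 40), rep("SS", 40))
  cand <- enumerate_candidates(random_rna(80), state)
  spans <- cand$protospacer_start <= 40 & cand$protospacer_end >= 41
  expect_equal(cand$covers_junction, spans)
})
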