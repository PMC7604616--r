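# Sequence-level analysis: degenerate scanning, GA windows and regions,
# overlap, enrichment, deletion arithmetic, probe classification.

test_that("scan_motif matches the consensus under IUPAC rules", {
  expect_equal(scan_motif("AGAAGAA")$start, 1L)
  expect_equal(scan_motif("GGAAGGG")$start, 1L)  # all-R choices are purines
  expect_equal(nrow(scan_motif("CGAAGAA")), 0L)  # C is not a purine
  # overlapping matches are all reported, sorted
  expect_equal(scan_motif("AGAAGAAGAAGAA")$start, c(1L, 4L, 7L))
  hits <- scan_motif(list(id = "u1", sequence = "TTAGAAGAATT"))
  expect_equal(hits$utr_id, "u1")
  expect_equal(hits$matched, "AGAAGAA")
  expect_equal(hits$end - hits$start + 1, 7)
})

test_that("sequence normalization maps U to T and names bad residues", {
  expect_equal(normalize_sequence("augc"), "ATGC")
  expect_error(normalize_sequence("ACGNNT"), "position 4")
  expect_error(normalize_sequence(""), "non-empty")
})

test_that("scanning agrees with Biostrings degenerate matching", {
  set.seed(11)
  for (i in 1:25) {
    s <- random_acgt(sample(30:300, 1), prob = c(0.35, 0.15, 0.35, 0.15))
    got <- scan_motif(s)$start
    ref <- Biostrings::start(Biostrings::matchPattern(
      "RGAAGRR", Biostrings::DNAString(s), fixed = "subject"))
    expect_equal(got, as.integer(ref))
  }
})

test_that("ga_profile computes windowed GA fractions", {
  expect_equal(ga_profile(strrep("G", 30))$ga_fraction, 1.0)
  expect_equal(ga_profile(strrep("C", 30))$ga_fraction, 0.0)
  # dinucleotide repeat: every window is exactly half G+A regardless of phase
  s2 <- strrep("GT", 17)  # 34 nt
  prof2 <- ga_profile(s2)
  expect_equal(prof2$ga_fraction, rep(0.5, 5))
  # 4-periodic repeat truncated to 33 nt: 30-nt windows are phase-dependent
  # (30 is not a multiple of 4); frozen from the direct count oracle
  s <- substr(strrep("GACT", 9), 1, 33)
  prof <- ga_profile(s)
  expect_equal(prof$window_start, 1:4)
  expect_equal(prof$ga_fraction, c(16, 15, 14, 15) / 30)
  expect_equal(prof$ga_fraction, oracle_ga_windows(s))
  expect_error(ga_profile(strrep("A", 10)), "shorter than window")
})

test_that("GA-rich regions are maximal merged unions of qualifying windows", {
  s <- paste0(strrep("T", 30), strrep("GA", 20), strrep("T", 30))
  r <- detect_ga_rich_regions(s)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(24L, 77L))  # frozen from window oracle
  expect_equal(nrow(detect_ga_rich_regions(strrep("CT", 40))), 0L)
  pure <- detect_ga_rich_regions(strrep("GA", 50))
  expect_equal(c(pure$start, pure$end, pure$ga_fraction), c(1, 100, 1.0))
})

test_that("region calling respects the strict > threshold", {
  # 24 GA in a 32-nt window is exactly 0.75: must NOT qualify under strict >
  s <- paste0(strrep("GA", 12), strrep("CT", 4))
  expect_equal(nrow(detect_ga_rich_regions(s, region_params(window = 32,
                                                            min_len = 32))),
               0L)
  # the same sequence holds 30-nt windows above 0.75 and does qualify there
  expect_gt(nrow(detect_ga_rich_regions(s, region_params(window = 30,
                                                         min_len = 30))), 0L)
})

test_that("scan, windows and regions match brute-force oracles", {
  set.seed(101)
  for (i in 1:60) {
    s <- random_acgt(sample(30:200, 1), prob = c(0.35, 0.15, 0.35, 0.15))
    expect_identical(scan_motif(s)$start, as.integer(oracle_scan(s)))
    expect_equal(ga_profile(s)$ga_fraction, oracle_ga_windows(s))
    got <- detect_ga_rich_regions(s)
    ref <- oracle_regions(s)
    expect_equal(cbind(got$start, got$end), cbind(ref$start, ref$end),
                 ignore_attr = TRUE)
  }
})

test_that("every region contains a qualifying window and none lies outside", {
  set.seed(7)
  for (i in 1:20) {
    s <- random_acgt(120, prob = c(0.4, 0.1, 0.4, 0.1))
    regs <- detect_ga_rich_regions(s)
    prof <- ga_profile(s)
    q <- prof$window_start[prof$ga_fraction > 0.75]
    for (j in seq_len(nrow(regs))) {
      inside <- q >= regs$start[j] & (q + 29) <= regs$end[j]
      expect_true(nrow(regs) == 0 || any(inside))
    }
    # every qualifying window lies within some region
    for (s0 in q)
      expect_true(any(regs$start <= s0 & (s0 + 29) <= regs$end))
  }
})

test_that("motif-in-region counting uses full containment", {
  hits <- data.frame(utr_id = "u", start = c(10, 40, 95), end = c(16, 46, 101))
  regs <- data.frame(utr_id = "u", start = 5, end = 50,
                     ga_fraction = 0.8)
  ov <- motif_region_overlap(hits, regs)
  expect_equal(ov$n_inside, 2L)      # the hit straddling 95..101 is outside
  expect_equal(ov$fraction, 2 / 3)
  # no regions -> fraction 0; no hits -> undefined
  expect_equal(motif_region_overlap(hits, regs[0, ])$fraction, 0)
  expect_true(is.na(motif_region_overlap(hits[0, ], regs)$fraction))
  # spanning region contains everything
  all_in <- motif_region_overlap(hits, data.frame(utr_id = "u", start = 1,
                                                  end = 200))
  expect_equal(all_in$fraction, 1.0)
  expect_error(motif_region_overlap(
    hits, data.frame(utr_id = "other", start = 1, end = 200)),
    "share no utr_id")
})

test_that("group summaries count motif-bearing UTRs per group", {
  with_motif <- paste0(strrep("CT", 20), "AGAAGAA", strrep("CT", 20))
  without <- strrep("CT", 40)
  recs <- utr_set(sprintf("u%02d", 1:10),
                  c(rep(with_motif, 6), rep(without, 4)),
                  rep("grpA", 10))
  summ <- summarize_groups(recs)
  expect_equal(unname(summ$group_fraction["grpA"]), 0.6)
  expect_equal(sum(summ$per_utr$has_motif), 6)
  pyr <- utr_set(c("p1", "p2"), rep(strrep("CT", 30), 2), rep("pyr", 2))
  expect_equal(unname(summarize_groups(pyr)$group_fraction["pyr"]), 0)
  expect_error(summarize_groups(rbind(recs, recs)), "duplicate ids")
})

test_that("motif enrichment is a two-sided Fisher test with Bonferroni", {
  same <- motif_enrichment(rep(c(TRUE, FALSE), each = 5),
                           rep(c(TRUE, FALSE), each = 5))
  expect_equal(same$p_value, 1.0)
  extreme <- motif_enrichment(rep(TRUE, 10), rep(FALSE, 10))
  expect_equal(extreme$p_value, 2 / choose(20, 10))  # enumeration closed form
  # Bonferroni definition and bounds
  p5 <- motif_enrichment(rep(TRUE, 10), rep(FALSE, 10), m_tests = 5)
  expect_equal(p5$p_bonferroni, min(1, 5 * p5$p_value))
  expect_error(motif_enrichment(c(TRUE), c(FALSE), m_tests = 0), "m_tests")
  expect_error(motif_enrichment(logical(0), c(TRUE)), "non-empty")
})

test_that("Fisher p is symmetric in group labels and decreases with divergence", {
  flags_a <- rep(c(TRUE, FALSE), c(7, 5))
  flags_b <- rep(c(TRUE, FALSE), c(3, 9))
  expect_equal(motif_enrichment(flags_a, flags_b)$p_value,
               motif_enrichment(flags_b, flags_a)$p_value)
  # at fixed group sizes, more divergent proportions give smaller p
  p <- vapply(0:5, function(k)
    motif_enrichment(rep(c(TRUE, FALSE), c(5 + k, 5 - k)),
                     rep(c(TRUE, FALSE), c(5 - k, 5 + k)))$p_value,
    numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("deletions splice sequences and remap downstream annotations", {
  expect_equal(apply_deletion("ACGTA",
                              data.frame(start = 2, end = 3))$sequence,
               "ATA")
  set.seed(3)
  s <- random_acgt(400)
  dpmo <- apply_deletion(s, data.frame(start = 202, end = 254))
  expect_equal(dpmo$removed_nt, 53L)
  expect_equal(nchar(dpmo$sequence), 400 - 53)
  d12 <- apply_deletion(s, data.frame(start = c(204, 193),
                                      end = c(211, 200)),
                        annotations = data.frame(start = 250, end = 256))
  expect_equal(d12$removed_nt, 16L)
  expect_equal(c(d12$annotations$start, d12$annotations$end),
               c(234, 240))  # shifted by the 16 nt removed upstream
  expect_error(apply_deletion(s, data.frame(start = c(10, 15),
                                            end = c(20, 25))), "overlap")
  expect_error(apply_deletion(s, data.frame(start = 390, end = 401)),
               "out of range")
  expect_warning(
    apply_deletion(s, data.frame(start = 202, end = 254),
                   annotations = data.frame(start = 250, end = 256)),
    "dropped")
})

test_that("rescanning a deleted UTR equals scanning the spliced string", {
  set.seed(23)
  for (i in 1:20) {
    s <- random_acgt(sample(60:200, 1), prob = c(0.35, 0.15, 0.35, 0.15))
    n <- nchar(s)
    st <- sort(sample(n - 8, 2))
    del <- data.frame(start = st, end = pmin(st + c(3, 5), n))
    if (del$start[2] <= del$end[1]) next
    spliced <- apply_deletion(s, del)$sequence
    keep <- setdiff(seq_len(n), unlist(Map(seq, del$start, del$end)))
    literal <- paste(strsplit(s, "")[[1]][keep], collapse = "")
    expect_identical(spliced, literal)
    expect_identical(scan_motif(spliced)$start,
                     as.integer(oracle_scan(literal)))
  }
})

test_that("probe classification uses any-overlap with motif priority", {
  regs <- data.frame(start = 98, end = 268)
  hits <- data.frame(start = c(165, 230), end = c(171, 236))
  expect_equal(classify_probe(230, 25, regs, hits), "overlaps_motif")
  expect_equal(classify_probe(98, 25, regs, hits[0, ]), "overlaps_ga_region")
  expect_equal(classify_probe(300, 25, regs, hits[0, ]), "outside")
  # inclusive-coordinate boundary: probe starting one past the region end
  expect_equal(classify_probe(269, 25, regs, hits[0, ]), "outside")
  expect_equal(classify_probe(268, 25, regs, hits[0, ]), "overlaps_ga_region")
  expect_error(classify_probe(300, 25, regs, hits, seq_length = 310),
               "out of sequence bounds")
})
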