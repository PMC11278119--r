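# Seven-pattern construction and the genome-wide homology scan.

test_that("patterns are exact concatenations of the decomposition", {
  dec <- structure(list(five_nr = "AA", units = c("CGT", "CGT"),
                        three_nr = "TT",
                        call = list(consensus = "CGT")),
                   class = "cr_decomposition")
  pats <- build_patterns(dec)
  expect_length(pats, 7)
  expect_identical(unname(pats[["5NR+TRunit+3NR"]]), "AACGTTT")
  expect_identical(unname(pats[["5NR+3NR"]]), "AATT")
  # empty 5NR drops the duplicate patterns with a warning
  dec$five_nr <- ""
  expect_warning(p2 <- build_patterns(dec), "degenerate")
  expect_length(p2, 3)  # TRunit, 3NR, TRunit+3NR collapse the rest
})

test_that("a planted 3NR copy at the rrnS 5' end is recovered at 100%", {
  cfg <- sim_config(seed = 1, order_type = "C", plant_rrns_overlap = TRUE,
                    cr2_spec = list(substitution_rate = 0))
  sim <- simulate_mitogenome(cfg)
  res <- scan_cr2_origin(sim$genome)
  hits <- res$hits
  expect_gt(nrow(hits), 0)
  h3 <- hits[hits$pattern == "3NR", , drop = FALSE]
  expect_equal(nrow(h3), 1)
  expect_equal(h3$identity_pct, 100)
  expect_identical(h3$target_start, sim$truth$homology$target_start)
  expect_identical(h3$target_end, sim$truth$homology$target_end)
  expect_match(h3$overlapping_features, "rrnS")
})

test_that("an unrelated random genome yields no hits", {
  withr::with_seed(13, {
    cfg <- sim_config(seed = 5, order_type = "C",
                      cr2_spec = list(substitution_rate = 0))
    sim <- simulate_mitogenome(cfg)
    dec <- scan_cr2_origin(sim$genome)$decomposition
    pats <- build_patterns(dec)
    other <- mitogenome("rand", random_dna(8000),
                        data.frame(name = "ND1", strand = "H",
                                   start = 0L, end = 900L))
    hits <- scan_genome(pats, other, min_identity = 90, min_length = 30)
    expect_equal(nrow(hits), 0)
  })
})

test_that("self-hits inside the excluded interval are suppressed", {
  withr::with_seed(14, {
    g <- mitogenome("self", random_dna(2000),
                    data.frame(name = c("ND1", "CR"), strand = "H",
                               start = c(0L, 1000L), end = c(900L, 1500L)))
    pat <- c(probe = substr(g$sequence, 1101, 1180))
    hits <- scan_genome(pat, g, exclude = c(1000L, 1500L))
    expect_equal(nrow(hits), 0)
    # without the exclusion the same probe is found
    hits2 <- scan_genome(pat, g)
    expect_gt(nrow(hits2), 0)
    expect_identical(hits2$target_start[1], 1100L)
  })
})

test_that("reported identities re-derive from the aligned strings", {
  cfg <- sim_config(seed = 3, order_type = "C", plant_rrns_overlap = TRUE,
                    cr2_spec = list(substitution_rate = 0))
  sim <- simulate_mitogenome(cfg)
  hits <- scan_cr2_origin(sim$genome)$hits
  for (r in seq_len(nrow(hits))) {
    a <- strsplit(hits$aligned_pattern[r], "")[[1]]
    b <- strsplit(hits$aligned_target[r], "")[[1]]
    expect_equal(hits$identity_pct[r],
                 100 * sum(a == b & a != "-") / length(a))
  }
})

test_that("both strands are scanned and strands flip with the genome", {
  withr::with_seed(15, {
    g <- mitogenome("fwd", random_dna(3000),
                    data.frame(name = "ND1", strand = "H",
                               start = 0L, end = 900L))
    pat <- c(probe = revcomp(substr(g$sequence, 501, 580)))
    hits <- scan_genome(pat, g)
    expect_gt(nrow(hits), 0)
    expect_identical(hits$strand[1], "L")
    expect_identical(hits$target_start[1], 500L)
    # scanning the reverse-complemented genome finds it on the H strand
    g_rc <- mitogenome("rev", revcomp(g$sequence),
                       data.frame(name = "ND1", strand = "H",
                                  start = 0L, end = 900L))
    hits_rc <- scan_genome(pat, g_rc)
    expect_gt(nrow(hits_rc), 0)
    expect_identical(hits_rc$strand[1], "H")
    # mirrored coordinates: start' = L - end
    expect_identical(hits_rc$target_start[1], 3000L - hits$target_end[1])
  })
})

test_that("a pattern spanning the circular origin is still found", {
  withr::with_seed(16, {
    s <- random_dna(2000)
    g <- mitogenome("circ", s,
                    data.frame(name = "ND1", strand = "H",
                               start = 0L, end = 900L))
    pat <- c(wrap = paste0(substr(s, 1961, 2000), substr(s, 1, 40)))
    hits <- scan_genome(pat, g)
    expect_gt(nrow(hits), 0)
    expect_identical(hits$target_start[1], 1960L)
    expect_identical(hits$target_end[1], 2040L)  # unwrapped past origin
  })
})
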