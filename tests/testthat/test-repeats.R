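# Tandem-repeat detection, CR decomposition, haplotype statistics and
# the folding proxy.

test_that("a clean planted array is recovered with exact boundaries", {
  spec <- list(five_nr_len = 60L, period = 37L, copies = 4,
               substitution_rate = 0, divergent_first_unit = FALSE,
               fused_halves = FALSE, three_nr_len = 40L)
  cr <- simulate_cr2(spec, seed = 2)
  calls <- detect_tandem_repeats(cr$sequence)
  expect_length(calls, 1)
  cl <- calls[[1]]
  expect_identical(cl$period, 37L)
  expect_equal(cl$copies, 4)
  expect_identical(cl$start, cr$truth$tr_start)
  expect_identical(cl$end, cr$truth$tr_end)
  dec <- decompose_cr(cr$sequence, cl)
  expect_identical(dec$five_nr, cr$truth$five_nr)
  expect_identical(dec$units, cr$truth$units)
  expect_identical(dec$three_nr, cr$truth$three_nr)
})

test_that("random sequence yields no calls", {
  withr::with_seed(9, {
    s <- random_dna(200)
    expect_length(detect_tandem_repeats(s, min_period = 10,
                                        min_copies = 1.9,
                                        min_identity = 80), 0)
  })
})

test_that("a fused two-subunit array reports the sub-period", {
  withr::with_seed(10, {
    spec <- list(five_nr_len = 50L, period = 64L, copies = 3,
                 substitution_rate = 0, divergent_first_unit = FALSE,
                 fused_halves = TRUE, three_nr_len = 30L)
    cr <- simulate_cr2(spec, seed = 10)
    calls <- detect_tandem_repeats(cr$sequence)
    expect_length(calls, 1)
    expect_identical(calls[[1]]$period, 64L)
    expect_true(32L %in% calls[[1]]$alt_periods)
    # and the consensus carries the fusion signature at the planted
    # half-divergence
    fus <- detect_subunit_fusion(calls[[1]]$consensus)
    expect_identical(fus$hamming, cr$truth$half_divergence)
  })
})

test_that("decomposition always concatenates exactly", {
  # call covering the whole CR leaves empty non-repeat regions
  unit <- "ACGTTGCAAC"
  cr <- strrep(unit, 3)
  calls <- detect_tandem_repeats(cr)
  expect_length(calls, 1)
  dec <- decompose_cr(cr, calls[[1]])
  expect_identical(dec$five_nr, "")
  expect_identical(dec$three_nr, "")
  expect_identical(paste(dec$units, collapse = ""), cr)
  # out-of-bounds call errors
  bad <- calls[[1]]; bad$end <- nchar(cr) + 5L
  expect_error(decompose_cr(cr, bad), "outside")
})

test_that("a truncated final partial unit is kept as the last unit", {
  withr::with_seed(15, {
    spec <- list(five_nr_len = 40L, period = 61L, copies = 3 + 26 / 61,
                 substitution_rate = 0, divergent_first_unit = FALSE,
                 fused_halves = FALSE, three_nr_len = 35L)
    cr <- simulate_cr2(spec, seed = 15)
    calls <- detect_tandem_repeats(cr$sequence)
    expect_length(calls, 1)
    dec <- decompose_cr(cr$sequence, calls[[1]])
    lens <- nchar(dec$units)
    expect_identical(lens[length(lens)], 26L)
    expect_true(all(lens[-length(lens)] == 61L))
    expect_identical(paste0(dec$five_nr, paste(dec$units, collapse = ""),
                            dec$three_nr), cr$sequence)
  })
})

test_that("consensus is the column majority with first-observed tie-break", {
  tab <- table1()
  ea <- tab$Eremophila_alpestris
  expect_identical(build_consensus(ea$haplotypes), ea$reference)
  expect_identical(build_consensus(c("ACGT", "ACGT", "ACGT")), "ACGT")
  withr::with_seed(4, {
    for (rep in 1:10) {
      master <- random_dna(20)
      units <- vapply(1:5, function(i) {
        x <- strsplit(master, "")[[1]]
        for (j in sample(20, 2))
          x[j] <- sample(setdiff(c("A", "C", "G", "T"), x[j]), 1)
        paste(x, collapse = "")
      }, "")
      # brute-force per-column majority with the same tie rule
      m <- do.call(rbind, strsplit(units, ""))
      expected <- vapply(seq_len(ncol(m)), function(j) {
        tb <- table(m[, j])
        top <- names(tb)[tb == max(tb)]
        if (length(top) == 1) top else m[m[, j] %in% top, j][1]
      }, "")
      expect_identical(build_consensus(units), paste(expected, collapse = ""))
    }
  })
})

test_that("divergent initial units are flagged, conserved ones are not", {
  tab <- table1()
  d <- tab$Alauda_arvensis$haplotypes
  expect_true(flag_divergent_initial_unit(d[c("D_1", "D_2", "D_3")]))
  a <- tab$Eremophila_alpestris$haplotypes
  expect_false(flag_divergent_initial_unit(a[c("A_1", "A_2", "A_3")]))
  expect_false(flag_divergent_initial_unit(c("ACGTACGTAC", "ACGTACGTAC")))
})

test_that("subunit fusion detection follows the printed combined unit", {
  tab <- table1()
  comb <- tab$Melanocorypha_mongolica$haplotypes[["H_1+H_2"]]
  fus <- detect_subunit_fusion(comb, max_diff_frac = 0.35)
  expect_identical(fus$hamming, 9L)
  expect_identical(fus$half_a, tab$Melanocorypha_mongolica$haplotypes[["H_1"]])
  expect_identical(detect_subunit_fusion("ACGTACGT")$hamming, 0L)
  # odd length is never a fusion
  expect_null(detect_subunit_fusion(tab$Eremophila_alpestris$reference))
  # halves too different
  expect_null(detect_subunit_fusion("AAAAATTTTT"))
})

test_that("similarity statistics reproduce the published ranges", {
  tab <- table1()
  ea <- unit_similarity_stats(tab$Eremophila_alpestris$haplotypes)
  expect_equal(round(ea$min_sim, 1), 98.0)
  expect_equal(ea$max_sim, 100)
  expect_equal(round(unit_similarity_stats(
    tab$Alauda_gulgula$haplotypes)$min_sim, 1), 92.9)
  expect_equal(unit_similarity_stats(
    tab$Alaudala_heinei$haplotypes)$min_sim, 100)
  # the exclusion rules leave B_6 out but keep the terminal-deletion
  # B_7, giving the printed 94.1-100.0 range
  rs <- repeat_unit_set(tab$Alaudala_cheleensis$haplotypes)
  expect_identical(names(rs$excluded)[rs$excluded], "B_6")
  expect_equal(round(rs$min_sim, 1), 94.1)
  expect_equal(rs$max_sim, 100)
  # single usable haplotype gives null statistics
  expect_null(unit_similarity_stats("ACGTACGT")$min_sim)
  # a deletion inside a slippage-prone TATA tract is still classified
  # as internal (local alignment would hide it as a mismatch), so the
  # C. cinerea range stays at the printed 100%
  g <- tab$Calandrella_cinerea$haplotypes
  expect_true(larkCR:::has_internal_deletion(g[["G_2"]], g[["G_3"]]))
  rg <- repeat_unit_set(g)
  expect_true(rg$divergent_initial)
  expect_setequal(names(rg$excluded)[rg$excluded], c("G_1", "G_3"))
  expect_equal(rg$min_sim, 100)
})

test_that("haplotype multiplicities sum to the unit count", {
  withr::with_seed(16, {
    spec <- list(five_nr_len = 30L, period = 24L, copies = 6,
                 substitution_rate = 0.02, divergent_first_unit = FALSE,
                 fused_halves = FALSE, three_nr_len = 30L)
    cr <- simulate_cr2(spec, seed = 16)
    rs <- repeat_unit_set(cr$truth$units)
    expect_equal(sum(rs$multiplicity), length(cr$truth$units))
  })
})

test_that("folding maximises Watson-Crick pairs", {
  expect_identical(fold_score("AAAAAA")$pairs, 0L)
  gga <- fold_score("GGGAAACCC", min_loop = 3)
  expect_identical(gga$pairs, 3L)
  expect_identical(gga$structure, "(((...)))")
  withr::with_seed(6, {
    for (rep in 1:12) {
      s <- substr(random_dna(40), 1, sample(8:15, 1))
      expect_identical(fold_score(s)$pairs,
                       as.integer(brute_fold_pairs(s)), label = s)
    }
  })
})

test_that("a substring's pairing score embeds into any superstring", {
  withr::with_seed(17, {
    for (rep in 1:10) {
      a <- random_dna(sample(3:10, 1))
      b <- random_dna(sample(3:14, 1))
      expect_gte(fold_score(paste0(a, b))$pairs, fold_score(b)$pairs)
    }
  })
})
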