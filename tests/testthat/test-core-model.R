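# Mitogenome container, I/O round trips, linearisation, gene-order
# extraction and classification.

toy_genome <- function() {
  feats <- data.frame(
    name = c("geneA", "trnX", "rrnZ"),
    strand = c("H", "L", "H"),
    start = c(0L, 40L, 60L),
    end = c(40L, 60L, 100L))
  suppressWarnings(mitogenome("toy", random_dna(100), feats))
}

test_that("FASTA + TSV round trip preserves the genome", {
  withr::with_seed(11, {
    g <- toy_genome()
    fa <- withr::local_tempfile(fileext = ".fasta")
    tsv <- withr::local_tempfile(fileext = ".tsv")
    write_mitogenome(g, fa, tsv)
    g2 <- suppressWarnings(read_mitogenome(fa, tsv))
    expect_identical(g2$sequence, g$sequence)
    expect_equal(nrow(g2$features), 3L)
    expect_identical(g2$features$start, g$features$start)
    expect_identical(g2$features$kind, g$features$kind)
  })
})

test_that("feature bounds are validated", {
  feats <- data.frame(name = "ND1", strand = "H", start = 60L, end = 110L)
  expect_error(mitogenome("bad", random_dna(100), feats), "wrap flag")
  feats$wrap <- TRUE
  expect_silent(mitogenome("ok", random_dna(100), feats))
  expect_error(
    mitogenome("dup", random_dna(100),
               data.frame(name = c("ND1", "ND1"), strand = "H",
                          start = c(0L, 50L), end = c(40L, 90L))),
    "unique")
})

test_that("multi-record FASTA is rejected", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGT"), fa)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines("name\tstrand\tstart\tend\nND1\tH\t0\t4", tsv)
  expect_error(read_mitogenome(fa, tsv), "exactly one record")
})

test_that("linearize rotates and is invertible", {
  withr::with_seed(12, {
    g <- toy_genome()
    r <- suppressWarnings(linearize(g, "trnX"))
    expect_equal(r$features$start[r$features$name == "trnX"], 0L)
    expect_equal(nchar(r$sequence), g$length)
    # rotating back to the original anchor restores the genome
    back <- suppressWarnings(linearize(r, "geneA"))
    expect_identical(back$sequence, g$sequence)
    expect_identical(back$features$start, g$features$start)
    # all feature shifts equal the anchor start mod length
    shift <- g$features$start[g$features$name == "trnX"]
    expect_identical(r$features$start,
                     sort((g$features$start - shift) %% g$length))
  })
})

test_that("linearize rejects missing or ambiguous anchors", {
  withr::with_seed(13, {
    g <- toy_genome()
    expect_error(linearize(g, "nope"), "not found")
    # two CR copies: anchoring on the shared symbol must fail
    f2 <- data.frame(name = c("CR1", "CR2"), strand = "H",
                     start = c(0L, 50L), end = c(40L, 90L))
    g2 <- mitogenome("toy2", g$sequence, f2)
    expect_error(linearize(g2, "CR"), "not unique")
  })
})

test_that("gene_sequence honours strand and circular wrap", {
  feats <- data.frame(name = c("wrapgene", "mid"),
                      strand = c("H", "L"),
                      start = c(90L, 40L), end = c(110L, 60L),
                      wrap = c(TRUE, FALSE))
  withr::with_seed(14, {
    seqn <- random_dna(100)
    g <- suppressWarnings(mitogenome("w", seqn, feats))
    expect_identical(gene_sequence(g, "wrapgene"),
                     paste0(substr(seqn, 91, 100), substr(seqn, 1, 10)))
    expect_identical(gene_sequence(g, "mid"),
                     revcomp(substr(seqn, 41, 60)))
  })
})

test_that("gene order equality is rotation-invariant but not reflective", {
  o <- order_C()
  for (k in seq_along(o$labels))
    expect_true(order_equal(o, larkCR:::rotate_order(o, k)))
  refl <- gene_order(rev(o$labels))
  expect_false(order_equal(o, refl))
  expect_false(order_equal(o, order_B()))
})

test_that("classification covers the published order types", {
  expect_identical(classify_gene_order(order_A()), "A")
  expect_identical(classify_gene_order(order_B()), "B")
  expect_identical(classify_gene_order(order_C()), "C")
  t1 <- parse_gene_order(paste0("Cytb,trnT,-trnP,-ND6,-trnE,CR1,",
                                "Cytb_2,trnT_2,-trnP_2,-ND6_2,-trnE_2,CR2,",
                                "trnF,rrnS"))
  expect_identical(classify_gene_order(t1), "T1")
  t3 <- parse_gene_order(paste0("Cytb,trnT,-trnP,-ND6,-trnE,CR1,",
                                "-trnP_2,-ND6_2,-trnE_2,CR2,trnF,rrnS"))
  expect_identical(classify_gene_order(t3), "T3")
  # classification is total: unknown duplication sets and odd CR counts
  expect_identical(classify_gene_order(parse_gene_order("ND1,ND1_2,CR")), "UN")
  expect_identical(classify_gene_order(parse_gene_order("ND1,ND2")), "UN")
  expect_identical(classify_gene_order(parse_gene_order("singleton")), "UN")
})

test_that("extract_gene_order recovers the planted arrangement", {
  for (ot in c("A", "B", "C", "T1", "T2", "T3")) {
    cfg <- sim_config(seed = 7, order_type = ot)
    sim <- simulate_mitogenome(cfg)
    expect_identical(classify_gene_order(extract_gene_order(sim$genome)), ot,
                     label = paste("order type", ot))
  }
})

test_that("simulator output read back from disk equals the truth record", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 1, order_type = "C")
  write_simulation(cfg, dir)
  g <- read_mitogenome(file.path(dir, "genome.fasta"),
                       file.path(dir, "annotation.tsv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_identical(g$features$name, truth$genome$features$name)
  expect_identical(g$features$start, as.integer(truth$genome$features$start))
  expect_identical(g$features$end, as.integer(truth$genome$features$end))
})
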