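# Fitch/Hartigan parsimony mapping and the repeat-association test.

test_that("newick parsing round trips", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_equal(length(tr$tip.label), 4)
  expect_equal(tr$Nnode, 3)
  expect_error(parse_newick("((A,B),(C,D"), "malformed")
  txt <- ape::write.tree(tr)
  expect_identical(ape::write.tree(parse_newick(txt)), txt)
})

test_that("uniform tips need no changes; a clean split needs one", {
  tr <- parse_newick("((A,B),(C,D));")
  f0 <- fitch_ancestral(tr, c(A = "1", B = "1", C = "1", D = "1"))
  expect_identical(f0$n_changes, 0L)
  expect_equal(nrow(f0$changes), 0)
  f1 <- fitch_ancestral(tr, c(A = "1", B = "1", C = "0", D = "0"))
  expect_identical(f1$n_changes, 1L)
  expect_equal(nrow(f1$changes), 1)
  # the down pass places the change on one cherry stem
  expect_gt(f1$changes$child[1], 4)
})

test_that("change counts equal the exhaustive minimum on small trees", {
  withr::with_seed(8, {
    for (rep in 1:12) {
      ntip <- sample(4:10, 1)
      tr <- ape::rtree(ntip)
      tr$tip.label <- paste0("t", seq_len(ntip))
      states <- setNames(sample(c("B", "C", "A"), ntip, replace = TRUE),
                         tr$tip.label)
      ft <- fitch_ancestral(tr, states)
      expect_identical(ft$n_changes, as.integer(brute_fitch_min(tr, states)))
      # recorded branch changes realise exactly that minimum
      expect_identical(nrow(ft$changes), as.integer(ft$n_changes))
    }
  })
})

test_that("multifurcations are handled exactly", {
  tr <- parse_newick("((A,B,C),(D,E));")
  states <- c(A = "1", B = "0", C = "1", D = "0", E = "0")
  ft <- fitch_ancestral(tr, states)
  expect_identical(ft$n_changes, as.integer(brute_fitch_min(tr, states)))
})

test_that("adding a tip matching its sister does not increase changes", {
  withr::with_seed(9, {
    for (rep in 1:8) {
      ntip <- sample(4:8, 1)
      tr <- ape::rtree(ntip)
      tr$tip.label <- paste0("t", seq_len(ntip))
      states <- setNames(sample(c("0", "1"), ntip, replace = TRUE),
                         tr$tip.label)
      base <- fitch_ancestral(tr, states)$n_changes
      # graft a new tip next to tip t1 carrying t1's state
      nwk2 <- sub("t1:", "(t1:9,tnew:9):", ape::write.tree(tr), fixed = TRUE)
      tr2 <- parse_newick(nwk2)
      states2 <- c(states, tnew = unname(states["t1"]))
      expect_lte(fitch_ancestral(tr2, states2)$n_changes, base)
    }
  })
})

test_that("a lark-like fixture maps a single origin of order C", {
  # Alaudidae + Panurus carry order C; the rest of the Sylvioidea-like
  # tree carries B: one origin on the stem of their shared clade
  nwk <- paste0("(((((Alauda,Eremophila),Melanocorypha),Panurus),",
                "(Hirundo,Acrocephalus)),(Parus,Passer));")
  tr <- parse_newick(nwk)
  states <- c(Alauda = "C", Eremophila = "C", Melanocorypha = "C",
              Panurus = "C", Hirundo = "B", Acrocephalus = "B",
              Parus = "B", Passer = "B")
  ft <- fitch_ancestral(tr, states)
  expect_identical(ft$n_changes, 1L)
  org <- origin_branches(ft, "C")
  expect_equal(nrow(org), 1)
  # the origin branch subtends exactly the C clade
  sub <- ape::extract.clade(tr, org$child[1])
  expect_setequal(sub$tip.label,
                  c("Alauda", "Eremophila", "Melanocorypha", "Panurus"))
})

test_that("missing tip states error unless explicitly allowed", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_error(fitch_ancestral(tr, c(A = "1", B = "1", C = "0")),
               "missing tip state")
  ft <- fitch_ancestral(tr, c(A = "1", B = "1", C = "0"),
                        allow_missing = TRUE)
  expect_equal(length(ft$tree$tip.label), 3)
})

test_that("fisher p matches enumeration, fisher.test, and its invariances", {
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)), 2 / 252)
  expect_equal(fisher_exact(matrix(c(3, 3, 0, 0), 2, byrow = TRUE)), 1)
  expect_error(fisher_exact(matrix(0, 2, 2)), "all-zero")
  withr::with_seed(20, {
    for (rep in 1:25) {
      tab <- matrix(rpois(4, 3), 2, 2)
      if (sum(tab) == 0 || sum(tab) > 20) next
      p <- fisher_exact(tab)
      expect_equal(p, brute_fisher(tab), tolerance = 1e-10)
      expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
      expect_true(p > 0 && p <= 1 + 1e-12)
      expect_equal(fisher_exact(t(tab)), p, tolerance = 1e-10)
      expect_equal(fisher_exact(tab[2:1, 2:1]), p, tolerance = 1e-10)
    }
  })
})

test_that("trait tables round trip and feed the mapping", {
  sim <- simulate_traits_on_tree(8, change_branches = 12L, seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(sim$traits, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  states <- read_trait_table(path, "order_type")
  expect_identical(unname(states[sim$traits$tip]), sim$traits$order_type)
  ft <- fitch_ancestral(sim$tree, states)
  expect_lte(ft$n_changes, 1L)
})
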