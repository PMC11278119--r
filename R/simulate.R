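# Synthetic avian mitogenomes with known ground truth.
#
# The simulator fabricates the structures this package analyses — a
# standard avian gene complement arranged in one of the CR-duplication
# order types, a CR1 with planted conserved boxes, and a remnant CR2
# built as 5NR + tandem units + 3NR — so that every pipeline stage can
# be exercised against an explicit truth record, offline. Gene
# sequences are random with correct start/stop codons: the pipeline
# analyses the structure, not the biology, of those regions. All
# randomness flows from a single integer seed; sub-seeds are derived
# by fixed offsets so each component is reproducible in isolation.

# default conserved-box motifs planted in CR1 (presence/absence markers
# of a complete control region; the literal sequences are arbitrary
# fixed anchors, not biological consensus motifs)
default_cr1_boxes <- function() c(
  ETAS1 = "TACATAATACATTAATGTA",
  ETAS2 = "CATAAACATTAATG",
  Fbox  = "ATGGCCCTGACTTAAC",
  Ebox  = "AGGGACCCCTCAGT",
  Dbox  = "CCTGGTTCCTAGG",
  Cbox  = "ACGTCCATAACG",
  bbox  = "TCAAGTGCTAG",
  Bbox  = "CCGGACATAGC",
  CSB1  = "TTCAAACCCCCCTACCCCCC")

#' Simulation configuration
#'
#' @param seed integer master seed; all randomness derives from it.
#' @param order_type gene-order type to plant: A, B, C, T1, T2 or T3.
#' @param cr1_boxes named character vector of conserved-box motifs
#'   planted, in order, across CR1's three domains.
#' @param cr2_spec list describing the remnant CR2: `five_nr_len`,
#'   `period`, `copies` (may be fractional; a trailing partial unit is
#'   planted), `substitution_rate` (per-base, per unit, in [0, 0.2]),
#'   `divergent_first_unit`, `fused_halves` (build the unit as two
#'   diverged half-units, the combined-repeat pattern), `three_nr_len`.
#' @param plant_rrns_overlap copy the 3' end of the 3NR onto the 5' end
#'   of rrnS (at most 81 nt), emulating the observed rCR2-3NR/rrnS
#'   homology, so the scan stage has a planted positive.
#' @param genome_length_target approximate target length in bp (guides
#'   the PCG length draws; the realised length varies).
#' @return `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       order_type = c("C", "A", "B", "T1", "T2", "T3"),
                       cr1_boxes = default_cr1_boxes(),
                       cr2_spec = list(five_nr_len = 60L, period = 37L,
                                       copies = 4, substitution_rate = 0.01,
                                       divergent_first_unit = FALSE,
                                       fused_halves = FALSE,
                                       three_nr_len = 40L),
                       plant_rrns_overlap = FALSE,
                       genome_length_target = 17000L) {
  order_type <- match.arg(order_type)
  spec <- utils::modifyList(list(five_nr_len = 60L, period = 37L, copies = 4,
                                 substitution_rate = 0.01,
                                 divergent_first_unit = FALSE,
                                 fused_halves = FALSE, three_nr_len = 40L),
                            cr2_spec)
  if (spec$substitution_rate < 0 || spec$substitution_rate > 0.2)
    stop("substitution_rate must lie in [0, 0.2]")
  if (spec$period < 10) stop("period must be >= 10")
  if (spec$copies < 2) stop("copies must be >= 2")
  if (spec$fused_halves && spec$period %% 2 != 0)
    stop("fused_halves requires an even period")
  structure(list(seed = as.integer(seed), order_type = order_type,
                 cr1_boxes = cr1_boxes, cr2_spec = spec,
                 plant_rrns_overlap = isTRUE(plant_rrns_overlap),
                 genome_length_target = as.integer(genome_length_target)),
            class = "sim_config")
}

mutate_seq <- function(seq, rate = NULL, n_sub = NULL) {
  x <- s2c(seq)
  idx <- if (!is.null(n_sub)) {
    if (n_sub == 0) integer(0) else sample(seq_along(x), n_sub)
  } else which(stats::runif(length(x)) < rate)
  for (i in idx) x[i] <- sample(setdiff(DNA_BASES, x[i]), 1)
  c2s(x)
}

#' Simulate a remnant CR2
#'
#' Builds `5NR + units + 3NR` with i.i.d. random non-repeat regions and
#' tandem units derived from a random master unit by per-unit
#' substitutions. Optionally the first unit is strongly diverged
#' (substitutions at ~25% of its positions) and/or the master unit is a
#' fusion of two half-units differing at `round(0.28 * period / 2)`
#' positions. The bases flanking the array are constrained to differ
#' from the base one period away, so the planted array boundary is the
#' unique maximal one and the ground truth is well defined.
#'
#' @param spec list as in [sim_config()]'s `cr2_spec`.
#' @param seed integer seed.
#' @return List with `sequence` and `truth` (five_nr, units, three_nr,
#'   0-based `tr_start`/`tr_end`, `unit_starts`, `period`, `copies`,
#'   `half_divergence` when fused).
#' @export
simulate_cr2 <- function(spec, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    p <- as.integer(spec$period)
    n_full <- floor(spec$copies)
    partial_len <- round((spec$copies - n_full) * p)
    half_div <- NULL
    if (isTRUE(spec$fused_halves)) {
      half <- random_dna(p %/% 2)
      half_div <- as.integer(max(1, round(0.28 * p / 2)))
      other <- mutate_seq(half, n_sub = half_div)
      master <- paste0(half, other)
    } else {
      master <- random_dna(p)
    }
    units <- character(0)
    for (i in seq_len(n_full)) {
      u <- mutate_seq(master, rate = spec$substitution_rate)
      if (i == 1 && isTRUE(spec$divergent_first_unit))
        u <- mutate_seq(master, n_sub = max(3L, round(0.25 * p)))
      units <- c(units, u)
    }
    if (partial_len > 0)
      units <- c(units, substr(mutate_seq(master,
                                          rate = spec$substitution_rate),
                               1, partial_len))
    tr <- paste(units, collapse = "")
    five <- random_dna(spec$five_nr_len)
    three <- random_dna(spec$three_nr_len)
    # pin the array boundary: flanking bases must break the periodicity
    if (spec$five_nr_len > 0) {
      last5 <- substr(five, spec$five_nr_len, spec$five_nr_len)
      inside <- substr(tr, p, p)  # base one period downstream of last5
      if (last5 == inside) {
        five <- paste0(substr(five, 1, spec$five_nr_len - 1),
                       sample(setdiff(DNA_BASES, inside), 1))
      }
    }
    if (spec$three_nr_len > 0) {
      first3 <- substr(three, 1, 1)
      inside <- substr(tr, nchar(tr) - p + 1, nchar(tr) - p + 1)
      if (first3 == inside) {
        three <- paste0(sample(setdiff(DNA_BASES, inside), 1),
                        substr(three, 2, spec$three_nr_len))
      }
    }
    seqn <- paste0(five, tr, three)
    unit_starts <- spec$five_nr_len +
      c(0L, cumsum(nchar(units)))[seq_along(units)]
    list(sequence = seqn,
         truth = list(five_nr = five, units = units, three_nr = three,
                      tr_start = spec$five_nr_len,
                      tr_end = spec$five_nr_len + nchar(tr),
                      unit_starts = as.integer(unit_starts),
                      period = p,
                      copies = nchar(tr) / p,
                      master = master,
                      half_divergence = half_div))
  })
}

# fixed typical stop codon and sense-codon pools for the vertebrate
# mitochondrial code (table 2)
mito_sense_codons <- function() {
  gc <- mito_code()
  names(gc)[gc != "*"]
}

random_cds <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  ncod <- len / 3 - 2
  paste0("ATG", c2s(sample(mito_sense_codons(), ncod, replace = TRUE)), "TAA")
}

sim_gene_layout <- function(order_type) {
  H <- "H"; L <- "L"
  tail_block <- switch(order_type,
    A  = list(c("Cytb", H), c("trnT", H), c("trnP", L), c("ND6", L),
              c("trnE", L), c("CR", H), c("trnF", H)),
    B  = list(c("Cytb", H), c("trnT", H), c("CR1", H), c("trnP", L),
              c("ND6", L), c("trnE", L), c("CR2", H), c("trnF", H)),
    C  = list(c("Cytb", H), c("trnT", H), c("CR1", H), c("trnP", L),
              c("ND6", L), c("trnE", L), c("rCR2", H), c("trnF", H)),
    T1 = list(c("Cytb", H), c("trnT", H), c("trnP", L), c("ND6", L),
              c("trnE", L), c("CR1", H), c("Cytb_2", H), c("trnT_2", H),
              c("trnP_2", L), c("ND6_2", L), c("trnE_2", L), c("CR2", H),
              c("trnF", H)),
    T2 = list(c("Cytb", H), c("trnT", H), c("trnP", L), c("ND6", L),
              c("trnE", L), c("CR1", H), c("trnT_2", H), c("trnP_2", L),
              c("ND6_2", L), c("trnE_2", L), c("CR2", H), c("trnF", H)),
    T3 = list(c("Cytb", H), c("trnT", H), c("trnP", L), c("ND6", L),
              c("trnE", L), c("CR1", H), c("trnP_2", L), c("ND6_2", L),
              c("trnE_2", L), c("CR2", H), c("trnF", H)))
  head_block <- list(
    c("rrnS", H), c("trnV", H), c("rrnL", H), c("trnL2", H), c("ND1", H),
    c("trnI", H), c("trnQ", L), c("trnM", H), c("ND2", H), c("trnW", H),
    c("trnA", L), c("trnN", L), c("trnC", L), c("trnY", L), c("COX1", H),
    c("trnS2", L), c("trnD", H), c("COX2", H), c("trnK", H), c("ATP8", H),
    c("ATP6", H), c("COX3", H), c("trnG", H), c("ND3", H), c("trnR", H),
    c("ND4L", H), c("ND4", H), c("trnH", H), c("trnS1", H), c("trnL1", H),
    c("ND5", H))
  c(tail_block, head_block)
}

build_cr1 <- function(boxes) {
  spacer <- function() random_dna(sample(20:50, 1))
  paste0(paste(vapply(boxes, function(b) paste0(spacer(), b), ""),
               collapse = ""), spacer())
}

#' Simulate a complete mitogenome with ground truth
#'
#' Generates a circular avian-style mitogenome (13 PCGs, 22 tRNAs, two
#' rRNAs and the control regions implied by the order type), with a
#' CR1 carrying the configured conserved boxes and — for the
#' duplicated-CR types — a remnant or complete CR2. Returns the genome
#' and a truth record (planted features, CR2 decomposition, order
#' label, planted homology interval).
#'
#' @param config a [sim_config()].
#' @return List with `genome` (a `mitogenome`) and `truth`.
#' @export
simulate_mitogenome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  cr2 <- simulate_cr2(config$cr2_spec, seed = seed + 101L)
  withr::with_seed(seed + 202L, {
    layout <- sim_gene_layout(config$order_type)
    # scale PCG length draws so the realised total tracks the target
    non_pcg <- 22 * 70 + 950 + 1550 + 1500 + nchar(cr2$sequence)
    pcg_total <- max(13 * 320, config$genome_length_target - non_pcg)
    mean_pcg <- pcg_total / 13
    seqs <- character(length(layout))
    names_v <- character(length(layout))
    strands <- character(length(layout))
    for (i in seq_along(layout)) {
      nm <- layout[[i]][1]; st <- layout[[i]][2]
      base <- sub("_\\d+$", "", nm)
      kind <- guess_kind(base)
      s <- if (kind == "tRNA") random_dna(sample(65:75, 1))
      else if (base == "rrnS") random_dna(sample(930:990, 1))
      else if (base == "rrnL") random_dna(sample(1500:1620, 1))
      else if (kind == "CR") {
        if (base %in% c("rCR2")) cr2$sequence
        else if (base %in% c("CR", "CR1")) build_cr1(config$cr1_boxes)
        else build_cr1(config$cr1_boxes)  # a complete CR2 mirrors CR1
      }
      else {  # PCG
        len <- 3 * round(stats::runif(1, 0.55 * mean_pcg, 1.45 * mean_pcg) / 3)
        len <- max(309, min(1800, len))
        random_cds(len)
      }
      seqs[i] <- if (st == "L") revcomp(s) else s
      names_v[i] <- nm
      strands[i] <- st
    }
    ends <- cumsum(nchar(seqs))
    starts <- c(0L, ends[-length(ends)])
    genome_seq <- paste(seqs, collapse = "")
    truth_hom <- NULL
    if (config$plant_rrns_overlap && config$order_type %in% c("B", "C")) {
      three <- cr2$truth$three_nr
      klen <- min(81L, nchar(three))
      if (klen >= 1) {
        i_rrns <- which(names_v == "rrnS")
        s0 <- starts[i_rrns]
        piece <- substr(three, nchar(three) - klen + 1, nchar(three))
        genome_seq <- paste0(substr(genome_seq, 1, s0),
                             piece,
                             substr(genome_seq, s0 + klen + 1,
                                    nchar(genome_seq)))
        truth_hom <- list(pattern = "3NR", target_start = s0,
                          target_end = s0 + klen, feature = "rrnS",
                          length = klen)
      }
    }
    features <- data.frame(name = names_v, strand = strands,
                           start = starts, end = ends,
                           stringsAsFactors = FALSE)
    genome <- mitogenome(paste0("sim", seed), genome_seq, features)
    cr2_name <- if (config$order_type == "A") NA_character_
      else if (config$order_type %in% c("B", "T1", "T2", "T3")) "CR2"
      else "rCR2"
    list(genome = genome,
         truth = list(order_type = config$order_type,
                      features = features,
                      cr2_name = cr2_name,
                      cr2 = cr2$truth,
                      homology = truth_hom,
                      seed = seed))
  })
}

#' Simulate a trait-annotated phylogeny
#'
#' Generates a random rooted binary tree and evolves a discrete trait
#' along it: the root carries `states[1]` and the trait switches (to
#' the next state in `states`) on each branch listed in
#' `change_branches` (child-node ids of the generated tree). A
#' two-state repeat-presence pair (`cr1_repeat`, `cr2_repeat`) is also
#' drawn, with `cr2_repeat` tied to the derived trait state.
#'
#' @param tips number of tips.
#' @param change_branches integer child-node ids of branches carrying a
#'   planted state switch (possibly empty).
#' @param seed integer seed.
#' @param states state labels, default `c("B", "C")`.
#' @return List with `tree` (phylo), `traits` (data.frame: tip,
#'   order_type, cr1_repeat, cr2_repeat) and `truth` (planted origins).
#' @export
simulate_traits_on_tree <- function(tips, change_branches = integer(0),
                                    seed = 1L, states = c("B", "C")) {
  withr::with_seed(as.integer(seed), {
    tree <- ape::rtree(tips, rooted = TRUE)
    tree$tip.label <- paste0("sp", seq_len(tips))
    ntip <- tips
    root <- ntip + 1L
    state_of <- character(ntip + tree$Nnode)
    state_of[root] <- states[1]
    pre <- ape::reorder.phylo(tree, "postorder")$edge
    pre <- pre[rev(seq_len(nrow(pre))), , drop = FALSE]
    for (r in seq_len(nrow(pre))) {
      parent <- pre[r, 1]; child <- pre[r, 2]
      s <- state_of[parent]
      if (child %in% change_branches) {
        pos <- match(s, states)
        s <- states[min(pos + 1L, length(states))]
      }
      state_of[child] <- s
    }
    tip_states <- state_of[seq_len(ntip)]
    traits <- data.frame(
      tip = tree$tip.label,
      order_type = tip_states,
      cr1_repeat = sample(c(TRUE, FALSE), ntip, replace = TRUE,
                          prob = c(0.15, 0.85)),
      cr2_repeat = tip_states == states[length(states)],
      stringsAsFactors = FALSE)
    list(tree = tree, traits = traits,
         truth = list(change_branches = as.integer(change_branches),
                      node_states = state_of, states = states))
  })
}

#' Write a simulation to disk in public formats
#'
#' Writes `genome.fasta`, `annotation.tsv`, `tree.nwk`, `traits.tsv`
#' and `truth.json` so that consumer tests can round-trip through the
#' same file formats real data would use.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param tips,change_branches forwarded to
#'   [simulate_traits_on_tree()].
#' @return Invisibly, the list of written paths.
#' @export
write_simulation <- function(config, dir, tips = 12,
                             change_branches = integer(0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_mitogenome(config)
  tt <- simulate_traits_on_tree(tips, change_branches,
                                seed = config$seed + 303L)
  paths <- list(
    fasta = file.path(dir, "genome.fasta"),
    annotation = file.path(dir, "annotation.tsv"),
    tree = file.path(dir, "tree.nwk"),
    traits = file.path(dir, "traits.tsv"),
    truth = file.path(dir, "truth.json"))
  write_mitogenome(sim$genome, paths$fasta, paths$annotation)
  ape::write.tree(tt$tree, paths$tree)
  utils::write.table(tt$traits, paths$traits, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(genome = sim$truth, tree = tt$truth),
                       paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
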