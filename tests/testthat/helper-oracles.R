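# Independent oracle implementations used to cross-check the package's
# algorithms on small inputs. These deliberately use different
# mechanics from the implementation they test.

# --- local alignment: exhaustive enumeration over substring pairs ----
# Enumerates every gapped alignment of every substring pair (affine gap
# cost: open + extend for the first gap base, extend for each further
# base) and returns the best score. Exponential; for tiny strings only.
enum_global_best <- function(xv, yv, p) {
  best <- -Inf
  n <- length(xv); m <- length(yv)
  rec <- function(i, j, prev, sc) {
    if (i > n && j > m) {
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i <= n && j <= m)
      rec(i + 1, j + 1, "M",
          sc + if (xv[i] == yv[j]) p$match else p$mismatch)
    if (i <= n)
      rec(i + 1, j, "X",
          sc - if (prev == "X") p$gap_extend else p$gap_open + p$gap_extend)
    if (j <= m)
      rec(i, j + 1, "Y",
          sc - if (prev == "Y") p$gap_extend else p$gap_open + p$gap_extend)
  }
  rec(1, 1, "S", 0)
  best
}

oracle_local_score <- function(a, b, p = align_params()) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- 0
  for (i1 in seq_along(av)) for (i2 in i1:length(av)) {
    for (j1 in seq_along(bv)) for (j2 in j1:length(bv)) {
      s <- enum_global_best(av[i1:i2], bv[j1:j2], p)
      if (s > best) best <- s
    }
  }
  best
}

# --- local alignment: independent dynamic-programming implementation -
biostrings_local_score <- function(a, b, p = align_params()) {
  mat <- matrix(p$mismatch, 4, 4,
                dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  diag(mat) <- p$match
  as.numeric(Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = p$gap_open, gapExtension = p$gap_extend,
    scoreOnly = TRUE))
}

# --- TDRL: brute-force enumeration on plain token vectors ------------
# tokens are signed symbols; CR tokens are literally "CR"
rot_equal_tokens <- function(x, y) {
  if (length(x) != length(y)) return(FALSE)
  sx <- paste0("|", paste(c(y, y), collapse = "|"), "|")
  grepl(paste0("|", paste(x, collapse = "|"), "|"), sx, fixed = TRUE)
}

brute_tdrl <- function(src, tgt, window_from) {
  # src, tgt: signed token vectors; block must end at the single "CR"
  n <- length(src)
  base <- function(tok) sub("^-", "", tok)
  cr_at <- which(base(src) == "CR")
  stopifnot(length(cr_at) == 1)
  wstart <- which(base(src) == window_from)
  # rotate so window start is position 1
  rot <- src[((seq_len(n) - 1 + (wstart - 1)) %% n) + 1]
  cr_pos <- which(base(rot) == "CR")[1]
  found <- list()
  for (bs in seq_len(cr_pos)) {
    block <- rot[bs:cr_pos]
    dup <- c(rot[seq_len(cr_pos)], block[base(block) != "CR" | TRUE])
    layout <- c(rot[seq_len(bs - 1)], block, block,
                if (cr_pos < n) rot[(cr_pos + 1):n])
    copyid <- c(rep(0, bs - 1), rep(1, length(block)), rep(2, length(block)),
                rep(0, n - cr_pos))
    non_cr <- which(base(block) != "CR")
    k <- length(non_cr)
    grids <- if (k == 0) list(integer(0)) else
      asplit(as.matrix(expand.grid(rep(list(1:2), k))), 1)
    for (g in grids) {
      drop <- rep(FALSE, length(layout))
      ok <- TRUE
      for (t in seq_len(k)) {
        tok <- block[non_cr[t]]
        hit <- which(layout == tok & copyid == g[t])
        if (length(hit) != 1) { ok <- FALSE; break }
        drop[hit] <- TRUE
      }
      if (!ok) next
      res <- layout[!drop]
      if (rot_equal_tokens(res, tgt))
        found[[length(found) + 1]] <- list(block = block, choice = g)
    }
  }
  found
}

# --- Fitch: exhaustive minimisation over internal labelings ----------
brute_fitch_min <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  states <- sort(unique(as.character(tip_states)))
  nn <- tree$Nnode
  edge <- tree$edge
  tip_vec <- as.character(tip_states[tree$tip.label])
  grid <- as.matrix(expand.grid(rep(list(states), nn)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- c(tip_vec, grid[r, ])
    ch <- sum(lab[edge[, 1]] != lab[edge[, 2]])
    if (ch < best) best <- ch
  }
  best
}

# --- Fisher: enumeration with explicit binomial coefficients ---------
brute_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  N <- r1 + r2
  prob <- function(a) {
    choose(c1, a) * choose(c2, r1 - a) / choose(N, r1)
  }
  xs <- max(0, c1 - r2):min(r1, c1)
  ps <- vapply(xs, prob, 0)
  pobs <- prob(tab[1, 1])
  sum(ps[ps <= pobs * (1 + 1e-7)])
}

# --- folding: exhaustive enumeration of nested structures ------------
brute_fold_pairs <- function(seq, min_loop = 3) {
  x <- strsplit(seq, "")[[1]]
  pairable <- function(a, b)
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G")
  rec <- function(avail) {
    if (length(avail) < 2) return(0)
    i <- avail[1]
    best <- rec(avail[-1])
    for (k in avail[-1]) {
      if (k - i - 1 < min_loop) next
      if (pairable(x[i], x[k])) {
        inside <- avail[avail > i & avail < k]
        outside <- avail[avail > k]
        v <- 1 + rec(inside) + rec(outside)
        if (v > best) best <- v
      }
    }
    best
  }
  rec(seq_along(x))
}

# --- shared tiny fixtures --------------------------------------------
order_A <- function() parse_gene_order("Cytb,trnT,-trnP,-ND6,-trnE,CR,trnF,rrnS")
order_B <- function() parse_gene_order("Cytb,trnT,CR1,-trnP,-ND6,-trnE,CR2,trnF,rrnS")
order_C <- function() parse_gene_order("Cytb,trnT,CR1,-trnP,-ND6,-trnE,rCR2,trnF,rrnS")

table1 <- function() suppressWarnings(read_repeat_unit_table())
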