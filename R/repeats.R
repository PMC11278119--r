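# Tandem-repeat detection and control-region decomposition.
#
# The detector is a purpose-built re-implementation of the usual
# period-finding approach: repeated k-mers propose candidate periods
# via their occurrence-distance histogram; for each candidate period
# (smallest first, so the fundamental period wins over its multiples)
# the self-match profile at that offset delimits candidate arrays,
# whose unit boundaries are then refined against the array consensus.
# See the package vignette for the boundary and phase conventions.

pct_id <- function(u, v) 100 * mean(u == v)

divisors_of <- function(p) {
  d <- seq_len(p %/% 2)
  d[p %% d == 0]
}

#' Detect tandem repeats in a (control-region) sequence
#'
#' Returns maximal non-overlapping tandem-repeat calls. Each call
#' records the array extent (0-based half-open coordinates), the unit
#' period, the real-valued copy number, the per-unit start offsets, the
#' array consensus, and any alternative sub-periods (divisors of the
#' period at which the array still shows elevated self-similarity —
#' the signature of a unit that arose by fusion of two smaller units).
#'
#' A full leading unit that is noticeably diverged from the array
#' consensus (identity below `min_identity` but at least
#' `divergent_include`) is included in the array: such divergent first
#' units are a real feature of lark rCR2 arrays. A trailing partial
#' unit is grown by exact match to the consensus prefix and kept when
#' it reaches at least `min_partial` nt; units always tile from the
#' array start.
#'
#' @param seq DNA string, at least `2 * min_period` long.
#' @param min_period minimum unit length (bp), default 10.
#' @param min_copies minimum copy number, default 1.9.
#' @param min_identity minimum unit-to-consensus identity (percent),
#'   default 80.
#' @param max_period maximum unit length; default `floor(nchar(seq)/2)`.
#' @param min_partial minimum length (nt) of a leading/trailing partial
#'   unit, default 5.
#' @param divergent_include identity floor (percent) for including a
#'   divergent full first unit, default 50.
#' @return List of `tandem_repeat_call` objects sorted by start
#'   (empty list when nothing qualifies).
#' @export
detect_tandem_repeats <- function(seq, min_period = 10, min_copies = 1.9,
                                  min_identity = 80, max_period = NULL,
                                  min_partial = 5, divergent_include = 50) {
  assert_dna(seq, "seq", allow_n = FALSE)
  L <- nchar(seq)
  if (L < 2 * min_period)
    stop("sequence shorter than 2 * min_period")
  if (is.null(max_period)) max_period <- L %/% 2
  x <- s2c(seq)
  thr <- min_identity / 100

  # candidate periods from the k-mer recurrence-distance histogram
  k <- 7L
  starts <- 1:(L - k + 1)
  kmers <- substring(seq, starts, starts + k - 1)
  pos_by <- split(starts, kmers)
  dd <- unlist(lapply(pos_by, function(p) if (length(p) > 1) diff(p)),
               use.names = FALSE)
  dd <- dd[dd >= min_period & dd <= max_period]
  if (!length(dd)) return(list())
  tb <- table(dd)
  cand <- sort(as.integer(names(tb)[tb >= 2L]))

  calls <- list()
  claimed <- rep(FALSE, L)
  for (p in cand) {
    if (2 * p > L) next
    m <- x[1:(L - p)] == x[(1 + p):L]
    lm <- length(m)
    if (lm < p) next
    cm <- c(0, cumsum(m))
    nw <- lm - p + 1
    roll <- (cm[(p + 1):(p + nw)] - cm[1:nw]) / p
    good <- roll >= thr
    if (!any(good)) next
    r <- rle(good)
    rends <- cumsum(r$lengths)
    rstarts <- rends - r$lengths + 1
    for (ri in which(r$values)) {
      # anchor: the window with maximal self-match identity (first of
      # the maxima), guaranteed to sit inside the array
      win <- rstarts[ri]:rends[ri]
      i0 <- win[which.max(roll[win])]
      call <- refine_repeat_call(x, i0, p, thr, min_partial,
                                 divergent_include, min_copies,
                                 min_period)
      if (is.null(call)) next
      span <- (call$start + 1):call$end
      if (any(claimed[span])) next
      claimed[span] <- TRUE
      calls[[length(calls) + 1L]] <- call
    }
  }
  calls[order(vapply(calls, function(cl) cl$start, 0))]
}

# Refine an array around anchor block i0 (1-based) at period p: walk
# block-by-block in both directions at threshold identity against the
# evolving consensus, optionally admit one diverged full leading unit,
# then extend a trailing partial unit by exact consensus match.
refine_repeat_call <- function(x, i0, p, thr, min_partial,
                               divergent_include, min_copies, min_period) {
  L <- length(x)
  if (i0 + p - 1 > L) return(NULL)
  block_at <- function(s) x[s:(s + p - 1)]
  cons <- block_at(i0)
  # walk left then right in steps of p, accepting blocks at >= thr
  s <- i0
  while (s - p >= 1 && pct_id(block_at(s - p), cons) >= 100 * thr) s <- s - p
  e <- i0
  while (e + 2 * p - 1 <= L && pct_id(block_at(e + p), cons) >= 100 * thr)
    e <- e + p
  n_full <- (e - s) %/% p + 1L
  if (n_full < 2) return(NULL)
  blocks <- lapply(seq_len(n_full) - 1L, function(t) block_at(s + t * p))
  cons <- consensus_chars(blocks)
  # second pass with the real consensus (the anchor block may carry
  # private mutations)
  while (s - p >= 1 && pct_id(block_at(s - p), cons) >= 100 * thr) {
    s <- s - p; n_full <- n_full + 1L
  }
  while (e + 2 * p - 1 <= L && pct_id(block_at(e + p), cons) >= 100 * thr) {
    e <- e + p; n_full <- n_full + 1L
  }
  arr_start <- s
  arr_end <- e + p - 1L

  # one diverged full leading unit (a real feature of these arrays)
  divergent <- FALSE
  if (arr_start - p >= 1) {
    id_pre <- pct_id(block_at(arr_start - p), cons)
    if (id_pre >= divergent_include && id_pre < 100 * thr) {
      arr_start <- arr_start - p
      divergent <- TRUE
      n_full <- n_full + 1L
    }
  }

  # trailing partial unit by exact consensus match, kept when at least
  # min_partial nt
  t_len <- 0L
  while (arr_end + t_len + 1 <= L && t_len < p - 1 &&
         x[arr_end + t_len + 1] == cons[t_len + 1]) t_len <- t_len + 1L
  if (t_len >= min_partial) arr_end <- arr_end + t_len else t_len <- 0L

  copies <- (arr_end - arr_start + 1) / p
  if (copies < min_copies) return(NULL)
  unit_starts <- arr_start + (seq_len(n_full) - 1L) * p
  if (t_len > 0) unit_starts <- c(unit_starts, arr_start + n_full * p)

  # alternative sub-periods: divisors with elevated self-similarity
  alt <- integer(0)
  for (d in divisors_of(p)) {
    if (d < min_period) next
    i1 <- arr_start:(arr_end - d)
    if (pct_id(x[i1], x[i1 + d]) >= 60) alt <- c(alt, d)
  }

  structure(list(start = arr_start - 1L,      # 0-based half-open
                 end = arr_end,
                 period = as.integer(p),
                 copies = copies,
                 unit_starts = as.integer(unit_starts - 1L),
                 consensus = c2s(cons),
                 divergent_first = divergent,
                 alt_periods = alt),
            class = "tandem_repeat_call")
}

#' @export
print.tandem_repeat_call <- function(x, ...) {
  cat(sprintf(
    "<tandem repeat> [%d, %d) period %d, %.2f copies%s%s\n",
    x$start, x$end, x$period, x$copies,
    if (x$divergent_first) ", divergent first unit" else "",
    if (length(x$alt_periods))
      paste0(", alt period ", paste(x$alt_periods, collapse = "/")) else ""))
  invisible(x)
}

consensus_chars <- function(blocks) {
  mat <- do.call(rbind, blocks)
  apply_majority(mat)
}

apply_majority <- function(mat) {
  vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    tb <- table(col)
    top <- names(tb)[tb == max(tb)]
    if (length(top) == 1) return(top)
    # tie: take the first-observed unit's base among the tied ones
    for (b in col) if (b %in% top) return(b)
    top[1]
  }, "")
}

#' Decompose a control region around a tandem-repeat call
#'
#' Splits the CR into the 5' non-repeat region, the ordered repeat
#' units (the final unit may be a truncated partial), and the 3'
#' non-repeat region. The concatenation `5NR + units + 3NR` always
#' equals the input exactly.
#'
#' @param cr control-region DNA string.
#' @param call a `tandem_repeat_call` lying within `cr`.
#' @return `cr_decomposition` object: list with `five_nr`, `units`
#'   (character vector), `three_nr`, and the originating `call`.
#' @export
decompose_cr <- function(cr, call) {
  L <- nchar(cr)
  if (call$start < 0 || call$end > L)
    stop("tandem repeat call lies outside the control region")
  bounds <- c(call$unit_starts, call$end)
  units <- substring(cr, bounds[-length(bounds)] + 1, bounds[-1])
  out <- structure(list(
    five_nr = substr(cr, 1, call$start),
    units = units,
    three_nr = if (call$end < L) substr(cr, call$end + 1, L) else "",
    call = call), class = "cr_decomposition")
  if (paste0(out$five_nr, paste(out$units, collapse = ""), out$three_nr) != cr)
    stop("internal error: decomposition does not concatenate to the input")
  out
}

#' @export
print.cr_decomposition <- function(x, ...) {
  cat(sprintf("<rCR2 decomposition> 5NR %d nt | %d units (period %d) | 3NR %d nt\n",
              nchar(x$five_nr), length(x$units), x$call$period,
              nchar(x$three_nr)))
  invisible(x)
}

#' Majority-rule consensus of repeat units
#'
#' Per-column majority over the full-length units (those whose length
#' equals the modal unit length); ties are broken toward the base of
#' the first-observed unit carrying one of the tied bases.
#'
#' @param units character vector/list of unit sequences (at least one
#'   full-length unit).
#' @return Consensus DNA string of modal unit length.
#' @export
build_consensus <- function(units) {
  units <- as.character(unlist(units))
  if (!length(units)) stop("build_consensus: no units")
  lens <- nchar(units)
  tb <- table(lens)
  modal_lens <- as.integer(names(tb)[tb == max(tb)])
  ml <- lens[lens %in% modal_lens][1]  # tie: first-observed length
  full <- units[lens == ml]
  mat <- do.call(rbind, lapply(full, s2c))
  c2s(apply_majority(mat))
}

#' Flag a divergent initial repeat unit
#'
#' TRUE iff the first unit's local-alignment identity to the consensus
#' of the remaining units falls below `threshold` while every remaining
#' full-length unit is at least at `threshold` — the pattern shown by
#' the first repeat units of several larks, interpreted as units being
#' discarded during array evolution.
#'
#' @param units ordered unit sequences (>= 2).
#' @param threshold identity threshold in percent, default 90.
#' @param params alignment parameters.
#' @return Logical flag.
#' @export
flag_divergent_initial_unit <- function(units, threshold = 90,
                                        params = align_params()) {
  units <- as.character(unlist(units))
  if (length(units) < 2) return(FALSE)
  rest <- units[-1]
  cons <- build_consensus(rest)
  id1 <- local_align(units[1], cons, params)$identity_pct
  if (is.na(id1) || id1 >= threshold) return(FALSE)
  full <- rest[nchar(rest) == nchar(cons)]
  ids <- vapply(full, function(u) local_align(u, cons, params)$identity_pct, 0)
  all(ids >= threshold)
}

#' Detect a two-subunit fusion signature in a repeat unit
#'
#' An even-length unit whose two halves differ at no more than
#' `max_diff_frac` of their positions is reported as a candidate fusion
#' of two ancestral single units (the pattern behind the combined
#' H1+H2-style repeat units).
#'
#' @param consensus unit (consensus) sequence.
#' @param max_diff_frac maximum fraction of differing positions between
#'   the halves, default 0.35.
#' @return List with `half_a`, `half_b`, `hamming`, or NULL when the
#'   length is odd or the halves are too different.
#' @export
detect_subunit_fusion <- function(consensus, max_diff_frac = 0.35) {
  n <- nchar(consensus)
  if (n == 0 || n %% 2 == 1) return(NULL)
  half <- n %/% 2
  a <- substr(consensus, 1, half)
  b <- substr(consensus, half + 1, n)
  h <- hamming(a, b)
  if (h <= max_diff_frac * half)
    list(half_a = a, half_b = b, hamming = as.integer(h))
  else NULL
}

#' Build the haplotype summary of a repeat-unit array
#'
#' Collapses ordered units into distinct haplotypes with
#' multiplicities, builds the consensus, flags a divergent initial
#' unit and a subunit-fusion signature, and computes the pairwise
#' similarity statistics. Two kinds of haplotype are excluded from the
#' similarity statistics, mirroring how published per-species
#' similarity ranges are computed: (a) a divergent initial unit, and
#' (b) haplotypes whose deletion relative to the consensus is internal
#' rather than terminal (terminal truncations are retained because
#' local alignment trims them naturally).
#'
#' @param units ordered unit sequences of one array.
#' @param params alignment parameters.
#' @param divergent_threshold identity threshold (percent) for the
#'   divergent-initial-unit rule, default 90.
#' @return `repeat_unit_set` object: haplotypes, multiplicities,
#'   consensus, exclusion flags, similarity matrix, `min_sim`,
#'   `max_sim`, `divergent_initial`, `fusion`.
#' @export
repeat_unit_set <- function(units, params = align_params(),
                            divergent_threshold = 90) {
  units <- unlist(units)
  stopifnot(is.character(units))
  haplotypes <- units[!duplicated(units)]  # unique() would drop names
  multiplicity <- vapply(haplotypes, function(h) sum(units == h), 0L)
  divergent_initial <- flag_divergent_initial_unit(units,
                                                   divergent_threshold,
                                                   params)
  # a divergent first unit does not contribute to the consensus
  consensus <- build_consensus(if (divergent_initial) units[-1] else units)
  excluded <- vapply(haplotypes, function(h) has_internal_deletion(consensus, h),
                     NA)
  if (divergent_initial) excluded[haplotypes == units[1]] <- TRUE
  stats <- unit_similarity_stats_impl(haplotypes[!excluded], params)
  structure(list(haplotypes = haplotypes,
                 multiplicity = multiplicity,
                 consensus = consensus,
                 excluded = excluded,
                 similarity = stats$matrix,
                 min_sim = stats$min_sim,
                 max_sim = stats$max_sim,
                 divergent_initial = divergent_initial,
                 fusion = detect_subunit_fusion(consensus)),
            class = "repeat_unit_set")
}

# Internal-vs-terminal deletion is judged on the encoded difference
# mask against the consensus (the same codec that reads the printed
# haplotype tables): a deletion run that touches neither mask end is
# internal. Local alignment is the wrong judge here — a deletion
# inside a slippage-prone tract (e.g. a TATA run) can score better as
# an ungapped mismatch alignment and hide the deletion.
has_internal_deletion <- function(consensus, hap) {
  enc <- encode_diff_mask(consensus, hap)
  ref <- s2c(enc$reference)
  msk <- s2c(enc$mask)
  del <- msk == "-" & ref != "-"
  if (!any(del)) return(FALSE)
  runs <- rle(del)
  w <- which(runs$values)
  any(w != 1L & w != length(runs$values))
}

#' Pairwise similarity statistics of repeat-unit haplotypes
#'
#' Local-alignment identity (percent of alignment columns) over all
#' unordered pairs of non-excluded haplotypes.
#'
#' @param x a `repeat_unit_set`, or a character vector of haplotypes.
#' @param params alignment parameters.
#' @return List with `min_sim`, `max_sim` and the identity `matrix`
#'   (NULL elements when fewer than two usable haplotypes).
#' @export
unit_similarity_stats <- function(x, params = align_params()) {
  haps <- if (inherits(x, "repeat_unit_set")) x$haplotypes[!x$excluded]
          else as.character(unlist(x))
  unit_similarity_stats_impl(haps, params)
}

unit_similarity_stats_impl <- function(haps, params) {
  n <- length(haps)
  if (n < 2)
    return(list(min_sim = NULL, max_sim = NULL, matrix = NULL))
  mat <- matrix(NA_real_, n, n, dimnames = list(names(haps) %||% haps,
                                                names(haps) %||% haps))
  vals <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    id <- local_align(haps[i], haps[j], params)$identity_pct
    mat[i, j] <- mat[j, i] <- id
    vals <- c(vals, id)
  }
  list(min_sim = min(vals), max_sim = max(vals), matrix = mat)
}

#' @export
print.repeat_unit_set <- function(x, ...) {
  cat(sprintf("<repeat units> %d haplotypes (%d units), consensus %d nt\n",
              length(x$haplotypes), sum(x$multiplicity), nchar(x$consensus)))
  if (!is.null(x$min_sim))
    cat(sprintf("  similarity %.1f-%.1f%%\n", x$min_sim, x$max_sim))
  if (x$divergent_initial) cat("  divergent initial unit\n")
  if (!is.null(x$fusion))
    cat(sprintf("  subunit fusion signature (halves differ at %d sites)\n",
                x$fusion$hamming))
  invisible(x)
}
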