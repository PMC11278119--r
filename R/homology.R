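# Seven-pattern homology scan: where did the remnant CR2 come from?
#
# The rCR2 decomposition defines seven query patterns (5NR, the
# consensus repeat unit, 3NR, and their concatenations); each is
# scanned against the whole circular mitogenome on both strands with a
# deterministic seed-and-extend strategy (exact 12-mer seeds, local
# alignment extension), excluding the rCR2 itself.

#' Build the seven query patterns from a CR decomposition
#'
#' Patterns: `5NR`, `TRunit` (the array consensus), `3NR`,
#' `5NR+TRunit`, `TRunit+3NR`, `5NR+TRunit+3NR`, `5NR+3NR`. Composite
#' patterns are exact concatenations. When a component is empty the
#' patterns that would duplicate an existing one are dropped with a
#' warning.
#'
#' @param decomp a `cr_decomposition`.
#' @return Named character vector of patterns.
#' @export
build_patterns <- function(decomp) {
  five <- decomp$five_nr
  unit <- decomp$call$consensus %||% build_consensus(decomp$units)
  three <- decomp$three_nr
  if (!nzchar(five) && !nzchar(unit) && !nzchar(three))
    stop("build_patterns: all components empty")
  pats <- c("5NR" = five,
            "TRunit" = unit,
            "3NR" = three,
            "5NR+TRunit" = paste0(five, unit),
            "TRunit+3NR" = paste0(unit, three),
            "5NR+TRunit+3NR" = paste0(five, unit, three),
            "5NR+3NR" = paste0(five, three))
  empty <- !nzchar(pats)
  dupd <- duplicated(pats)
  if (any(empty | dupd)) {
    warning("empty decomposition component(s): ",
            sum(empty | dupd), " degenerate pattern(s) dropped")
    pats <- pats[!(empty | dupd)]
  }
  pats
}

build_kmer_index <- function(seq2, L, k = 12L) {
  starts <- 1:L
  split(starts, substring(seq2, starts, starts + k - 1L))
}

#' Scan a mitogenome for homologues of CR-derived patterns
#'
#' Deterministic seed-and-extend: exact `k`-mer matches between a
#' pattern and the doubled genome sequence (both strands) seed local
#' alignments of the pattern against the surrounding genomic window;
#' hits passing the identity and length thresholds are reported with
#' the genes they overlap. Hits overlapping the `exclude` interval
#' (normally the source rCR2) are suppressed, and circular duplicates
#' are collapsed modulo the genome length.
#'
#' @param patterns named character vector (see [build_patterns()]).
#' @param genome a `mitogenome`.
#' @param params alignment parameters.
#' @param min_identity minimum identity percent, default 85.
#' @param min_length minimum alignment columns, default 30.
#' @param exclude optional `c(start, end)` 0-based half-open genomic
#'   interval to suppress (self-hits).
#' @param k seed length, default 12.
#' @return data.frame of hits sorted by identity then length:
#'   `pattern`, `strand`, `target_start`, `target_end` (0-based
#'   half-open genome coordinates), `identity_pct`, `columns`, `score`,
#'   `overlapping_features`, plus aligned strings; zero rows when
#'   nothing is found.
#' @export
scan_genome <- function(patterns, genome, params = align_params(),
                        min_identity = 85, min_length = 30,
                        exclude = NULL, k = 12L) {
  L <- genome$length
  g2 <- paste0(genome$sequence, genome$sequence)
  idx <- build_kmer_index(g2, L, k)
  hits <- list()
  for (pname in names(patterns)) {
    for (strand in c("H", "L")) {
      pat <- if (strand == "H") patterns[[pname]] else revcomp(patterns[[pname]])
      np <- nchar(pat)
      if (np < k) next
      pstarts <- 1:(np - k + 1)
      pk <- substring(pat, pstarts, pstarts + k - 1L)
      diag_set <- integer(0)
      for (jj in seq_along(pk)) {
        gpos <- idx[[pk[jj]]]
        if (is.null(gpos)) next
        diag_set <- c(diag_set, gpos - pstarts[jj])
      }
      if (!length(diag_set)) next
      diag_set <- sort(unique(diag_set))
      # cluster nearby diagonals into one extension window each
      cl <- cumsum(c(1L, diff(diag_set) > np))
      for (ci in unique(cl)) {
        ds <- diag_set[cl == ci]
        w_start <- max(1L, min(ds) + 1L - np %/% 2L)
        w_end <- min(nchar(g2), max(ds) + np + np %/% 2L)
        win <- substr(g2, w_start, w_end)
        al <- local_align(pat, win, params)
        if (al$columns < min_length) next
        if (is.na(al$identity_pct) || al$identity_pct < min_identity) next
        ts <- w_start + al$start_b - 2L   # 0-based genome coordinate
        te <- w_start + al$end_b - 1L
        if (ts >= L) { ts <- ts - L; te <- te - L }  # circular dedupe
        if (!is.null(exclude) &&
            circ_overlap(ts, te, exclude[1], exclude[2], L)) next
        f <- genome$features
        ov <- vapply(seq_len(nrow(f)), function(i)
          circ_overlap(ts, te, f$start[i], f$end[i], L), NA)
        hits[[length(hits) + 1L]] <- data.frame(
          pattern = pname, strand = strand,
          target_start = ts, target_end = te,
          identity_pct = al$identity_pct, columns = al$columns,
          score = al$score,
          overlapping_features = paste(f$name[ov], collapse = ","),
          aligned_pattern = al$aligned_a, aligned_target = al$aligned_b,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(pattern = character(0), strand = character(0),
                      target_start = integer(0), target_end = integer(0),
                      identity_pct = numeric(0), columns = integer(0),
                      score = numeric(0),
                      overlapping_features = character(0),
                      aligned_pattern = character(0),
                      aligned_target = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[!duplicated(out[, c("pattern", "strand", "target_start",
                                 "target_end")]), , drop = FALSE]
  out <- out[order(-out$identity_pct, -out$columns), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan for the genomic origin of a remnant CR2
#'
#' Convenience pipeline: decomposes the named control region, builds
#' the seven patterns, and scans the rest of the genome for
#' homologues, excluding the CR itself.
#'
#' @param genome a `mitogenome` containing a CR feature named `cr_name`.
#' @param cr_name feature name of the remnant CR, default `"rCR2"`.
#' @param min_identity,min_length scan thresholds.
#' @param params alignment parameters.
#' @inheritParams detect_tandem_repeats
#' @return List with `decomposition`, `patterns`, `hits`.
#' @export
scan_cr2_origin <- function(genome, cr_name = "rCR2", params = align_params(),
                            min_identity = 85, min_length = 30,
                            min_period = 10, min_copies = 1.9) {
  cr <- gene_sequence(genome, cr_name)
  calls <- detect_tandem_repeats(cr, min_period = min_period,
                                 min_copies = min_copies)
  if (!length(calls)) stop("no tandem repeat found in ", cr_name)
  decomp <- decompose_cr(cr, calls[[1]])
  pats <- build_patterns(decomp)
  i <- which(genome$features$name == cr_name)
  exclude <- c(genome$features$start[i], genome$features$end[i])
  hits <- scan_genome(pats, genome, params, min_identity, min_length,
                      exclude = exclude)
  list(decomposition = decomp, patterns = pats, hits = hits)
}
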