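# Nucleotide composition, strand skew, RSCU and start/stop codons.

#' Base counts of a DNA string
#' @noRd
base_counts <- function(seq) {
  x <- s2c(seq)
  c(A = sum(x == "A"), C = sum(x == "C"), G = sum(x == "G"), T = sum(x == "T"))
}

#' Strand-skew and AT-content statistics
#'
#' AT-skew = (A - T)/(A + T) and GC-skew = (G - C)/(G + C), computed on
#' exact letter counts; `N` and other ambiguity codes are excluded from
#' all counts, and a zero denominator yields `NA` rather than 0.
#'
#' @param seq non-empty DNA string.
#' @return List with `at_skew`, `gc_skew` (dimensionless, in `[-1, 1]`)
#'   and `at_content` (percent of unambiguous bases).
#' @examples
#' compute_skew("AAAT")$at_skew  # 0.5
#' @export
compute_skew <- function(seq) {
  if (!nzchar(seq)) stop("compute_skew: empty sequence")
  n <- base_counts(toupper(seq))
  at <- n[["A"]] + n[["T"]]; gc <- n[["G"]] + n[["C"]]
  list(
    at_skew = if (at > 0) (n[["A"]] - n[["T"]]) / at else NA_real_,
    gc_skew = if (gc > 0) (n[["G"]] - n[["C"]]) / gc else NA_real_,
    at_content = if (at + gc > 0) 100 * at / (at + gc) else NA_real_)
}

# vertebrate mitochondrial genetic code (NCBI translation table 2)
mito_code <- function() {
  Biostrings::getGeneticCode("2")
}

#' Relative synonymous codon usage
#'
#' RSCU of each sense codon: observed count divided by the expected
#' count under uniform usage within its synonymous family (the family
#' mean). Within every family with non-zero usage the RSCU values sum to
#' the family size. Stop codons of the genetic code are excluded.
#'
#' @param cds_list character vector/list of CDS sequences, each given
#'   5'->3' on the coding strand; a trailing incomplete codon is
#'   trimmed. An internal stop codon triggers a warning with position.
#' @param code NCBI genetic code id; default `"2"` (vertebrate
#'   mitochondrial, as appropriate for avian mitogenomes and required
#'   for AGA/AGG stop codons).
#' @return data.frame with columns `codon`, `aa`, `count`, `rscu`
#'   (`NA` for families never used).
#' @export
compute_rscu <- function(cds_list, code = "2") {
  gc <- Biostrings::getGeneticCode(code)
  sense <- names(gc)[gc != "*"]
  counts <- stats::setNames(integer(length(sense)), sense)
  for (k in seq_along(cds_list)) {
    cds <- toupper(cds_list[[k]])
    usable <- nchar(cds) - nchar(cds) %% 3
    if (usable < 3) next
    codons <- substring(cds, seq(1, usable, 3), seq(3, usable, 3))
    ncod <- length(codons)
    aa <- gc[codons]
    internal_stop <- which(aa == "*" & seq_len(ncod) < ncod)
    if (length(internal_stop))
      warning(sprintf("internal stop codon in CDS %d at codon %s", k,
                      paste(internal_stop, collapse = ",")))
    # terminal stop codons are excluded from usage, as are codons with N
    keep <- codons[aa != "*" & codons %in% sense]
    if (length(keep)) {
      tb <- table(keep)
      counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
    }
  }
  aa <- gc[sense]
  rscu <- rep(NA_real_, length(sense))
  for (a in unique(aa)) {
    fam <- which(aa == a)
    tot <- sum(counts[fam])
    if (tot > 0) rscu[fam] <- counts[fam] / (tot / length(fam))
  }
  data.frame(codon = sense, aa = unname(aa), count = as.integer(counts),
             rscu = rscu, stringsAsFactors = FALSE)
}

#' Start and stop codon of a CDS
#'
#' @param cds CDS sequence 5'->3' on the coding strand, length >= 6.
#' @param flag_incomplete when TRUE (default) a CDS whose length is not
#'   a multiple of 3 reports its trailing 1-2 nt as an incomplete stop
#'   (mitochondrial stops are commonly completed by polyadenylation);
#'   when FALSE the trailing remainder is dropped and the last full
#'   codon is reported.
#' @return List with `start`, `stop`, and logical `incomplete`.
#' @examples
#' extract_start_stop("ATGGCCTAA")  # ATG / TAA
#' extract_start_stop("ATGGCCT")    # ATG / incomplete "T"
#' @export
extract_start_stop <- function(cds, flag_incomplete = TRUE) {
  cds <- toupper(cds)
  if (nchar(cds) < 6) stop("CDS shorter than 6 nt")
  start <- substr(cds, 1, 3)
  rem <- nchar(cds) %% 3
  if (rem > 0 && flag_incomplete) {
    list(start = start, stop = substr(cds, nchar(cds) - rem + 1, nchar(cds)),
         incomplete = TRUE)
  } else {
    usable <- nchar(cds) - rem
    list(start = start, stop = substr(cds, usable - 2, usable),
         incomplete = FALSE)
  }
}

#' Per-partition composition report for a mitogenome
#'
#' Computes skew statistics for the whole genome and for standard
#' partitions: concatenated PCGs, tRNAs, rRNAs, each control region,
#' and the three codon positions of the PCGs (coding-strand orientation).
#'
#' @param genome a `mitogenome`.
#' @return data.frame with one row per partition: `partition`,
#'   `length`, `at_content`, `at_skew`, `gc_skew`.
#' @export
composition_report <- function(genome) {
  f <- genome$features
  part_seq <- function(names) {
    paste(vapply(names, function(n) gene_sequence(genome, n), ""),
          collapse = "")
  }
  parts <- list(whole = genome$sequence,
                PCG = part_seq(f$name[f$kind == "PCG"]),
                tRNA = part_seq(f$name[f$kind == "tRNA"]),
                rRNA = part_seq(f$name[f$kind == "rRNA"]))
  for (cr in f$name[f$kind == "CR"]) parts[[cr]] <- gene_sequence(genome, cr)
  pcg <- part_seq(f$name[f$kind == "PCG"])
  if (nzchar(pcg)) {
    x <- s2c(pcg)
    usable <- length(x) - length(x) %% 3
    pos <- rep(1:3, length.out = usable)
    for (p in 1:3) parts[[paste0("codon", p)]] <- c2s(x[seq_len(usable)][pos == p])
  }
  rows <- lapply(names(parts), function(nm) {
    s <- parts[[nm]]
    if (!nzchar(s)) return(NULL)
    sk <- compute_skew(s)
    data.frame(partition = nm, length = nchar(s),
               at_content = sk$at_content, at_skew = sk$at_skew,
               gc_skew = sk$gc_skew, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
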