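# Circular mitogenome container and I/O.
#
# A Mitogenome is a light S3 object: the full H-strand sequence plus an
# ordered feature table. Coordinates are 0-based half-open everywhere
# inside the package; GFF3 input (1-based inclusive) is converted at the
# boundary. Features crossing the circular origin are stored unwrapped
# (end > genome length) and must carry wrap = TRUE in the annotation.

GENE_KINDS <- c("PCG", "tRNA", "rRNA", "CR")

guess_kind <- function(name) {
  base <- sub("_\\d+$", "", name)
  if (grepl("^trn", base)) "tRNA"
  else if (grepl("^rrn", base)) "rRNA"
  else if (grepl("^r?CR", base)) "CR"
  else "PCG"
}

KNOWN_GENES <- c(
  "ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6", "Cytb",
  "COX1", "COX2", "COX3", "ATP6", "ATP8",
  "rrnS", "rrnL",
  paste0("trn", c("F", "V", "L1", "L2", "I", "Q", "M", "W", "A", "N", "C",
                  "Y", "S1", "S2", "D", "K", "G", "R", "H", "E", "P", "T")),
  "CR", "CR1", "CR2", "rCR2")

#' Construct a circular mitogenome object
#'
#' @param id genome label or accession.
#' @param sequence upper-case DNA string (circular; alphabet A/C/G/T/N).
#' @param features data.frame with columns `name`, `strand` (H/L),
#'   `start`, `end` (0-based half-open), and optionally `kind`
#'   (PCG/tRNA/rRNA/CR; guessed from the name prefix when absent) and
#'   `wrap` (logical; TRUE for an origin-spanning feature whose
#'   unwrapped `end` exceeds the genome length).
#' @return A `mitogenome` object.
#' @export
mitogenome <- function(id, sequence, features) {
  sequence <- toupper(sequence)
  assert_dna(sequence, "genome sequence")
  L <- nchar(sequence)
  stopifnot(is.data.frame(features),
            all(c("name", "strand", "start", "end") %in% names(features)))
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (is.null(features$wrap)) features$wrap <- FALSE
  features$wrap <- as.logical(features$wrap)
  features$wrap[is.na(features$wrap)] <- FALSE
  if (is.null(features$kind) || all(is.na(features$kind)))
    features$kind <- vapply(features$name, guess_kind, "")
  unknown <- setdiff(sub("_\\d+$", "", features$name), KNOWN_GENES)
  if (length(unknown))
    warning("unknown gene symbol(s): ", paste(unknown, collapse = ", "),
            "; kind set by prefix heuristic")
  if (!all(features$strand %in% c("H", "L")))
    stop("feature strand must be 'H' or 'L'")
  if (any(features$start < 0) || any(features$start >= L))
    stop("feature start out of bounds")
  if (any(features$start >= features$end))
    stop("feature with start >= end (after unwrapping)")
  over <- features$end > L & !features$wrap
  if (any(over))
    stop("feature(s) beyond genome length without wrap flag: ",
         paste(features$name[over], collapse = ", "))
  if (any(features$end - features$start > L))
    stop("feature longer than genome")
  if (anyDuplicated(features$name))
    stop("feature names must be unique (suffix duplicate copies, e.g. trnP_2)")
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  structure(list(id = id, sequence = sequence,
                 features = features[, c("name", "strand", "start", "end",
                                         "kind", "wrap")],
                 length = L),
            class = "mitogenome")
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s: %d bp, %d features\n",
              x$id, x$length, nrow(x$features)))
  invisible(x)
}

#' Read a mitogenome from FASTA plus an annotation table
#'
#' @param fasta_path single-record FASTA file.
#' @param annotation_path feature table: either a TSV with header
#'   columns `name`, `strand`, `start`, `end` (0-based half-open,
#'   optional `kind`, `wrap`) or a GFF3 file (`.gff`/`.gff3`; 1-based
#'   inclusive, converted on read; requires the rtracklayer package).
#' @return A `mitogenome` object.
#' @export
read_mitogenome <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L)
    stop("FASTA must contain exactly one record, found ", length(seqs))
  id <- sub("\\s.*$", "", names(seqs)[1])
  sequence <- as.character(seqs[[1]])
  if (grepl("\\.gff3?$", annotation_path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package")
    gr <- rtracklayer::import(annotation_path)
    features <- data.frame(
      name = as.character(gr$Name %||% gr$ID),
      strand = ifelse(as.character(BiocGenerics::strand(gr)) == "-", "L", "H"),
      start = BiocGenerics::start(gr) - 1L,  # 1-based inclusive -> 0-based
      end = BiocGenerics::end(gr),
      stringsAsFactors = FALSE)
  } else {
    features <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  }
  mitogenome(id, sequence, features)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a mitogenome as FASTA plus a TSV annotation table
#'
#' @param genome a `mitogenome`.
#' @param fasta_path,annotation_path output paths.
#' @return Invisibly, the genome.
#' @export
write_mitogenome <- function(genome, fasta_path, annotation_path) {
  seq <- Biostrings::DNAStringSet(genome$sequence)
  names(seq) <- genome$id
  Biostrings::writeXStringSet(seq, fasta_path, width = 70L)
  utils::write.table(genome$features, annotation_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(genome)
}

#' Rotate a circular genome to start at an anchor gene
#'
#' Produces the canonical linearisation used for deterministic
#' comparisons: the sequence is rotated so the anchor's start becomes
#' position 0 and all features are re-coordinated (features that come to
#' span the new origin are unwrapped with `wrap = TRUE`).
#'
#' @param genome a `mitogenome`.
#' @param anchor gene name present exactly once.
#' @return The rotated `mitogenome`.
#' @export
linearize <- function(genome, anchor) {
  hit <- which(genome$features$name == anchor)
  if (length(hit) == 0L)  # fall back to copy-suffix-stripped symbols
    hit <- which(sub("_?\\d+$", "", genome$features$name) == anchor)
  if (length(hit) == 0L) stop("anchor gene not found: ", anchor)
  if (length(hit) > 1L) stop("anchor gene not unique: ", anchor)
  shift <- genome$features$start[hit]
  L <- genome$length
  if (shift == 0L) return(genome)
  seq <- paste0(substr(genome$sequence, shift + 1L, L),
                substr(genome$sequence, 1L, shift))
  f <- genome$features
  len <- f$end - f$start
  f$start <- (f$start - shift) %% L
  f$end <- f$start + len
  f$wrap <- f$end > L
  mitogenome(genome$id, seq, f)
}

#' Extract the feature sequence of a gene
#'
#' Returns the gene sequence 5'->3' on its coding strand (reverse
#' complemented for L-strand features); circular wrap is handled.
#'
#' @param genome a `mitogenome`.
#' @param name feature name.
#' @return DNA character scalar.
#' @export
gene_sequence <- function(genome, name) {
  i <- which(genome$features$name == name)
  if (length(i) != 1L) stop("feature not found or not unique: ", name)
  s <- genome$features$start[i]; e <- genome$features$end[i]
  L <- genome$length
  seq <- if (e <= L) substr(genome$sequence, s + 1L, e)
  else paste0(substr(genome$sequence, s + 1L, L),
              substr(genome$sequence, 1L, e - L))
  if (genome$features$strand[i] == "L") revcomp(seq) else seq
}
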