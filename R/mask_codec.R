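# Consensus/difference-mask codec for repeat-unit haplotype tables.
#
# A haplotype is printed as a mask over a reference (usually the
# per-species consensus): '.' marks identity with the reference column,
# '-' a deletion (or, on a column where the reference itself holds '-',
# the absence of an insertion), and a base letter a substitution (or an
# insertion where the reference column is '-'). Masks shorter than the
# reference are padded with trailing '-' (truncated final units are
# printed that way).

#' Decode a difference mask into a concrete haplotype sequence
#'
#' @param reference reference row; may contain `-` alignment-gap columns.
#' @param mask mask string over `. - A C G T`, at most as long as the
#'   reference (shorter masks are padded with trailing deletions).
#' @return The haplotype DNA string, deletions removed.
#' @examples
#' decode_diff_mask("ACGT", "..T.")
#' @export
decode_diff_mask <- function(reference, mask) {
  r <- s2c(reference)
  m <- s2c(mask)
  if (length(m) < length(r)) m <- c(m, rep("-", length(r) - length(m)))
  if (length(m) != length(r))
    stop("decode_diff_mask: mask longer than reference")
  bad <- setdiff(unique(m), c(".", "-", DNA_BASES, "N"))
  if (length(bad))
    stop("decode_diff_mask: invalid mask characters: ",
         paste(bad, collapse = " "))
  out <- character(length(r))
  for (i in seq_along(r)) {
    if (m[i] == "-") next
    if (m[i] == ".") {
      if (r[i] != "-") out[i] <- r[i]
    } else {
      if (m[i] == r[i])
        warning("decode_diff_mask: redundant substitution at column ", i)
      out[i] <- m[i]
    }
  }
  c2s(out[nzchar(out)])
}

#' Encode a haplotype as a difference mask against a reference
#'
#' Inverse of [decode_diff_mask()]: aligns the haplotype to the reference
#' (global alignment with unit mismatch cost and indel cost 1.25, so a
#' substitution is preferred over an insertion-deletion pair; ties are
#' broken diagonal first, then deletion) and emits the expanded reference
#' (with `-` columns at insertions) plus the mask. The round trip
#' `decode_diff_mask(enc$reference, enc$mask)` returns the haplotype.
#'
#' @param reference gap-free reference DNA string.
#' @param haplotype haplotype DNA string.
#' @return List with elements `reference` (possibly with inserted `-`
#'   columns) and `mask`, of equal length.
#' @export
encode_diff_mask <- function(reference, haplotype) {
  if (grepl("-", reference, fixed = TRUE))
    reference <- gsub("-", "", reference, fixed = TRUE)
  r <- s2c(reference); h <- s2c(haplotype)
  n <- length(r); m <- length(h)
  indel <- 1.25
  D <- matrix(0, n + 1, m + 1)
  P <- matrix(0L, n + 1, m + 1)  # 1 diag, 2 del (gap in hap), 3 ins
  D[, 1] <- (0:n) * indel
  D[1, ] <- (0:m) * indel
  P[2:(n + 1), 1] <- 2L
  if (m > 0) P[1, 2:(m + 1)] <- 3L
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      d <- D[i - 1, j - 1] + (r[i - 1] != h[j - 1])
      up <- D[i - 1, j] + indel
      le <- D[i, j - 1] + indel
      # at ties prefer a deletion, then the diagonal: with the
      # backwards traceback this pushes deletion runs toward the 3'
      # end, so truncated units encode as trailing dashes
      if (up <= d && up <= le)  { D[i, j] <- up; P[i, j] <- 2L }
      else if (d <= le)         { D[i, j] <- d; P[i, j] <- 1L }
      else                      { D[i, j] <- le; P[i, j] <- 3L }
    }
  }
  ref_out <- character(0); mask_out <- character(0)
  i <- n + 1L; j <- m + 1L
  while (i > 1L || j > 1L) {
    p <- P[i, j]
    if (p == 1L) {
      ref_out <- c(r[i - 1], ref_out)
      mask_out <- c(if (r[i - 1] == h[j - 1]) "." else h[j - 1], mask_out)
      i <- i - 1L; j <- j - 1L
    } else if (p == 2L) {
      ref_out <- c(r[i - 1], ref_out)
      mask_out <- c("-", mask_out)
      i <- i - 1L
    } else {
      ref_out <- c("-", ref_out)
      mask_out <- c(h[j - 1], mask_out)
      j <- j - 1L
    }
  }
  list(reference = c2s(ref_out), mask = c2s(mask_out))
}

#' Read a printed repeat-unit haplotype table
#'
#' Reads a TSV with columns `species`, `haplotype`, `role`, `row` where
#' `role` is `reference` (the per-species consensus / reference unit),
#' `mask` (a dot/dash difference mask over that reference) or `sequence`
#' (a plain sequence row). Masks are decoded against the most recent
#' reference row of the same species.
#'
#' @param path TSV path; defaults to the bundled table of lark rCR2
#'   repeat-unit haplotypes.
#' @return Named list (by species) of lists with elements `reference`
#'   (character scalar) and `haplotypes` (named character vector of
#'   decoded sequences).
#' @export
read_repeat_unit_table <- function(path = system.file(
  "extdata", "repeat_unit_haplotypes.tsv", package = "larkCR")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  stopifnot(all(c("species", "haplotype", "role", "row") %in% names(tab)))
  out <- list()
  for (sp in unique(tab$species)) {
    rows <- tab[tab$species == sp, , drop = FALSE]
    ref <- NULL
    haps <- character(0)
    for (k in seq_len(nrow(rows))) {
      role <- rows$role[k]
      if (role == "reference") {
        ref <- rows$row[k]
        # a consensus row (named *_CS) is not itself a haplotype; a
        # reference that is a real unit (e.g. a first repeat unit) is
        if (!grepl("CS$", rows$haplotype[k]))
          haps[[rows$haplotype[k]]] <- gsub("-", "", ref, fixed = TRUE)
      } else if (role == "mask") {
        if (is.null(ref)) stop("mask row before reference for ", sp)
        haps[[rows$haplotype[k]]] <- decode_diff_mask(ref, rows$row[k])
      } else if (role == "sequence") {
        haps[[rows$haplotype[k]]] <- rows$row[k]
      } else stop("unknown role: ", role)
    }
    out[[sp]] <- list(reference = ref, haplotypes = haps)
  }
  out
}
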