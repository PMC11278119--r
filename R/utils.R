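# Internal string helpers shared across modules. Sequences are plain
# upper-case character scalars; positions are 1-based inside R code and
# converted to the 0-based half-open external convention only at I/O
# boundaries.

s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

c2s <- function(x) paste(x, collapse = "")

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param seq DNA character scalar (A/C/G/T/N).
#' @return The reverse complement as a character scalar.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  comp <- chartr("ACGTN", "TGCAN", seq)
  c2s(rev(s2c(comp)))
}

#' Generate a random DNA string
#'
#' Uniform i.i.d. bases from the current RNG state; used by the simulator
#' and by tests.
#'
#' @param n length in bases.
#' @return Character scalar of length `n`.
#' @export
random_dna <- function(n) {
  c2s(sample(DNA_BASES, n, replace = TRUE))
}

assert_dna <- function(seq, what = "sequence", allow_n = TRUE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string")
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  if (grepl(sprintf("[^%s]", alphabet), seq))
    stop(what, " contains characters outside {", alphabet, "}")
  invisible(seq)
}

# circular [start, end) interval overlap on a genome of length L
# (0-based half-open, end may exceed L for wrapped intervals)
circ_overlap <- function(s1, e1, s2, e2, L) {
  span1 <- unique(rbind(c(s1 %% L, min(e1, s1 + L) %% L)))
  expand <- function(s, e) {
    s <- s %% L; len <- e - s
    if (len >= L) return(rbind(c(0, L)))
    e <- s + len
    if (e <= L) rbind(c(s, e)) else rbind(c(s, L), c(0, e - L))
  }
  a <- expand(s1, e1); b <- expand(s2, e2)
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a[i, 1] < b[j, 2] && b[j, 1] < a[i, 2]) return(TRUE)
  }
  FALSE
}
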