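# Base-pair-maximisation folding score.
#
# Repeat units that fold into stable stem-loops favour slipped-strand
# mispairing; as a simple, parameter-free stability proxy the package
# maximises the number of Watson-Crick pairs (Nussinov dynamic
# programme) instead of computing thermodynamic free energies.

wc_pair <- function(a, b) {
  (a == "A" && b == "T") || (a == "T" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G")
}

#' Maximal Watson-Crick pairing score of a single strand
#'
#' Nussinov base-pair maximisation restricted to A:T and G:C pairs with
#' a minimum hairpin loop of `min_loop` unpaired bases. Returns the
#' maximal pair count and one optimal structure in dot-bracket
#' notation (deterministic: unpaired-i is preferred at ties, then the
#' smallest pairing partner).
#'
#' @param seq DNA string.
#' @param min_loop minimum hairpin-loop length (nt), default 3.
#' @return `fold_score` object: list with `pairs` and `structure`.
#' @examples
#' fold_score("GGGAAACCC")$pairs  # 3
#' @export
fold_score <- function(seq, min_loop = 3) {
  x <- s2c(seq)
  n <- length(x)
  if (n == 0)
    return(structure(list(pairs = 0L, structure = ""), class = "fold_score"))
  N <- matrix(0L, n, n)
  if (n >= min_loop + 2) {
    for (len in (min_loop + 2):n) {
      for (i in 1:(n - len + 1)) {
        j <- i + len - 1
        best <- N[i + 1, j]  # i unpaired (preferred at ties)
        for (k in (i + min_loop + 1):j) {
          if (wc_pair(x[i], x[k])) {
            inner <- if (k - 1 >= i + 1) N[i + 1, k - 1] else 0L
            outer <- if (k + 1 <= j) N[k + 1, j] else 0L
            v <- 1L + inner + outer
            if (v > best) best <- v
          }
        }
        N[i, j] <- best
      }
    }
  }
  # traceback
  db <- rep(".", n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (i >= j || j - i < min_loop + 1) next
    if (N[i, j] == N[i + 1, j]) {
      stack[[length(stack) + 1L]] <- c(i + 1L, j)
      next
    }
    for (k in (i + min_loop + 1):j) {
      if (!wc_pair(x[i], x[k])) next
      inner <- if (k - 1 >= i + 1) N[i + 1, k - 1] else 0L
      outer <- if (k + 1 <= j) N[k + 1, j] else 0L
      if (N[i, j] == 1L + inner + outer) {
        db[i] <- "("; db[k] <- ")"
        if (k - 1 >= i + 1) stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
        if (k + 1 <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
        break
      }
    }
  }
  structure(list(pairs = N[1, n], structure = c2s(db)),
            class = "fold_score")
}

#' @export
print.fold_score <- function(x, ...) {
  cat(sprintf("<fold> %d pairs  %s\n", x$pairs, x$structure))
  invisible(x)
}
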