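# Signed circular gene orders and order-type classification.
#
# A GeneOrder is a circular list of gene symbols with strand signs plus
# a completeness state (complete/remnant) for each control-region copy.
# Equality is invariant under rotation but NOT under reflection: the
# mitochondrial strands are annotated, so a mirrored order is a
# different arrangement.

#' Construct a circular gene order
#'
#' @param labels character vector of gene symbols in circular genomic
#'   order; L-strand genes carry a leading `-` sign (e.g. `"-ND6"`).
#'   Control-region copies may be written `CR`, `CR1`, `CR2` or `rCR2`;
#'   an `rCR2` label implies the remnant state.
#' @param cr_states optional named character vector mapping CR labels to
#'   `"complete"` or `"remnant"`; defaults to remnant for labels starting
#'   with `r`, complete otherwise.
#' @return A `gene_order` object with fields `labels`, `symbols`
#'   (unsigned, duplicate-copy suffixes stripped), `strands`, and
#'   `cr_states` aligned with `labels` (`NA` for non-CR genes).
#' @examples
#' gene_order(c("Cytb", "trnT", "CR1", "-trnP", "-ND6", "-trnE",
#'              "rCR2", "trnF", "rrnS"))
#' @export
gene_order <- function(labels, cr_states = NULL) {
  stopifnot(is.character(labels), length(labels) >= 1L)
  strands <- ifelse(startsWith(labels, "-"), "L", "H")
  sym <- sub("^-", "", labels)
  sym <- sub("_\\d+$", "", sym)  # strip duplicate-copy suffixes
  is_cr <- grepl("^r?CR", sym)
  states <- rep(NA_character_, length(sym))
  states[is_cr] <- ifelse(startsWith(sym[is_cr], "r"), "remnant", "complete")
  if (!is.null(cr_states)) {
    for (nm in names(cr_states)) {
      hit <- which(sub("^-", "", labels) == nm)
      if (!length(hit)) stop("cr_states names a label not in the order: ", nm)
      states[hit] <- match.arg(cr_states[[nm]], c("complete", "remnant"))
    }
  }
  structure(list(labels = labels, symbols = sym, strands = strands,
                 cr_states = states),
            class = "gene_order")
}

#' Parse a comma-separated gene order string
#'
#' @param text e.g. `"Cytb,trnT,CR1,-trnP,-ND6,-trnE,rCR2,trnF,rrnS"`.
#' @inheritParams gene_order
#' @return A `gene_order`.
#' @export
parse_gene_order <- function(text, cr_states = NULL) {
  gene_order(trimws(strsplit(text, ",", fixed = TRUE)[[1]]), cr_states)
}

# canonical comparison tokens: strand sign + normalised symbol, CR
# copies collapsed to "CR" annotated with their completeness state
order_tokens <- function(order) {
  sym <- order$symbols
  tok <- ifelse(grepl("^r?CR", sym), paste0("CR/", order$cr_states), sym)
  paste0(ifelse(order$strands == "L", "-", ""), tok)
}

rotate_order <- function(order, k) {
  n <- length(order$labels)
  idx <- ((seq_len(n) - 1L + k) %% n) + 1L
  structure(list(labels = order$labels[idx], symbols = order$symbols[idx],
                 strands = order$strands[idx],
                 cr_states = order$cr_states[idx]),
            class = "gene_order")
}

#' Rotation-invariant equality of circular gene orders
#'
#' @param a,b `gene_order` objects.
#' @return TRUE iff one order is a rotation of the other (strand signs
#'   and CR completeness states must match; reflections do not count).
#' @export
order_equal <- function(a, b) {
  ta <- order_tokens(a); tb <- order_tokens(b)
  n <- length(ta)
  if (n != length(tb)) return(FALSE)
  for (k in 0:(n - 1)) {
    if (all(ta == tb[((seq_len(n) - 1L + k) %% n) + 1L])) return(TRUE)
  }
  FALSE
}

#' @export
print.gene_order <- function(x, ...) {
  cat("<gene_order> ", paste(x$labels, collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Extract the circular gene order of a mitogenome
#'
#' Features are taken in genomic (start) order; duplicate-copy suffixes
#' (`_2` etc.) are stripped from the symbols, and CR completeness is
#' read from the feature names (an `rCR2` feature is remnant).
#' Overlapping features of the same kind trigger a warning and are kept
#' ordered by start then end.
#'
#' @param genome a `mitogenome`.
#' @return A `gene_order`.
#' @export
extract_gene_order <- function(genome) {
  f <- genome$features
  f <- f[order(f$start, f$end), , drop = FALSE]
  if (nrow(f) > 1) {
    ov <- f$start[-1] < f$end[-nrow(f)] & f$kind[-1] == f$kind[-nrow(f)]
    if (any(ov))
      warning("overlapping features of the same kind; ordered by start, end")
  }
  labels <- paste0(ifelse(f$strand == "L", "-", ""), f$name)
  gene_order(labels)
}

#' Classify a gene order into the avian CR-duplication typology
#'
#' Types: `A` ancestral single-CR order; `B` two complete control
#' regions; `C` one complete CR plus one remnant CR (the lark
#' arrangement); `T1`/`T2`/`T3` transitional duplication states that
#' still retain an extra copy of, respectively, Cytb-trnT-trnP-ND6-trnE,
#' trnT-trnP-ND6-trnE, or trnP-ND6-trnE, between Cytb and rrnS; `UN`
#' anything else. The classification is total: every syntactically valid
#' order receives exactly one label.
#'
#' @param order a `gene_order`.
#' @return One of `"A"`, `"B"`, `"C"`, `"T1"`, `"T2"`, `"T3"`, `"UN"`.
#' @export
classify_gene_order <- function(order) {
  sym <- order$symbols
  is_cr <- grepl("^r?CR", sym)
  dup <- unique(sym[!is_cr][duplicated(sym[!is_cr])])
  if (length(dup)) {
    dupset <- sort(dup)
    if (setequal(dupset, c("Cytb", "trnT", "trnP", "ND6", "trnE"))) return("T1")
    if (setequal(dupset, c("trnT", "trnP", "ND6", "trnE"))) return("T2")
    if (setequal(dupset, c("trnP", "ND6", "trnE"))) return("T3")
    return("UN")
  }
  states <- order$cr_states[is_cr]
  n_complete <- sum(states == "complete")
  n_remnant <- sum(states == "remnant")
  if (n_complete == 1 && n_remnant == 0) return("A")
  if (n_complete == 2 && n_remnant == 0) return("B")
  if (n_complete == 1 && n_remnant == 1) return("C")
  "UN"
}

#' Serialise a gene order to JSON
#'
#' @param order a `gene_order`.
#' @param path optional file path; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
gene_order_json <- function(order, path = NULL) {
  js <- jsonlite::toJSON(list(labels = order$labels,
                              cr_states = as.list(stats::setNames(
                                order$cr_states[!is.na(order$cr_states)],
                                order$labels[!is.na(order$cr_states)]))),
                         auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
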