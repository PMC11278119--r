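# Tandem-duplication-random-loss (TDRL) scenarios between circular
# gene orders.
#
# Under TDRL a contiguous gene block is duplicated in tandem and one
# copy of each redundant gene is subsequently lost. Control regions are
# special: both CR copies survive (degradation of CR2 to a remnant is
# an annotation change, not a gene loss), which is what leaves the
# duplicated-CR orders B and C behind.

# locate a contiguous block c(from, to) by gene symbols on the circular
# order; returns the rotation offset and the block indices in that
# rotation
locate_block <- function(order, block) {
  sym <- order$symbols
  n <- length(sym)
  from <- which(sym == block[1])
  to <- which(sym == block[2])
  if (length(from) != 1L || length(to) != 1L)
    stop("block endpoints must occur exactly once: ",
         paste(block, collapse = ".."))
  rot <- from - 1L
  pos_to <- ((to - from) %% n) + 1L
  list(rot = rot, span = seq_len(pos_to))
}

#' Apply a tandem duplication followed by losses to a gene order
#'
#' The block `c(from, to)` (inclusive, in circular gene-symbol terms) is
#' duplicated in tandem; `losses` then removes single copies of
#' duplicated genes. Copy index 1 is the occurrence in the first
#' (upstream) block instance, 2 the one in the second.
#'
#' @param order a `gene_order`.
#' @param block character vector `c(from_symbol, to_symbol)`.
#' @param losses list of `c(gene_symbol, copy_index)` pairs (or a
#'   two-column matrix/data.frame); may be empty, giving the
#'   duplication intermediate itself.
#' @return The resulting `gene_order`.
#' @export
apply_tdrl <- function(order, block, losses = list()) {
  loc <- locate_block(order, block)
  rot <- rotate_order(order, loc$rot)
  n <- length(rot$labels)
  span <- loc$span
  idx <- c(span, span, setdiff(seq_len(n), span))
  copy <- c(rep(1L, length(span)), rep(2L, length(span)),
            rep(0L, n - length(span)))
  labels <- rot$labels[idx]
  sym <- rot$symbols[idx]
  states <- rot$cr_states[idx]
  if (is.data.frame(losses) || is.matrix(losses))
    losses <- lapply(seq_len(nrow(losses)), function(i) losses[i, ])
  drop <- logical(length(idx))
  for (ls in losses) {
    g <- as.character(ls[[1]]); ci <- as.integer(ls[[2]])
    if (!g %in% sym[copy > 0])
      stop("loss of a non-duplicated gene: ", g)
    hit <- which(sym == g & copy == ci)
    if (!length(hit)) stop("no copy ", ci, " of ", g, " in the duplication")
    drop[hit] <- TRUE
    if (all(drop[sym == g & copy > 0]) && !any(sym == g & copy == 0))
      stop("loss of both copies of ", g)
  }
  keep <- !drop
  labels <- labels[keep]; sym2 <- sym[keep]; states <- states[keep]
  # disambiguate remaining duplicate labels
  dup_lab <- duplicated(labels)
  labels[dup_lab] <- paste0(labels[dup_lab], "_2")
  out <- gene_order(labels)
  out$cr_states <- states
  out
}

#' Enumerate single-event TDRL scenarios between two gene orders
#'
#' Considers every contiguous duplication block that contains the
#' control region and ends at its 3' boundary, starting anywhere inside
#' `window` (default the Cytb..CR neighbourhood — the configuration in
#' which the duplicated-CR avian orders arise), together with every
#' loss pattern that removes exactly one copy of each duplicated non-CR
#' gene while keeping both CR copies. Scenarios whose result equals
#' `target` up to rotation are returned, shortest block first.
#'
#' @param source,target `gene_order` objects over the same gene multiset
#'   (up to CR copy number).
#' @param window character `c(from_symbol, to_symbol)` within which
#'   blocks may start; default `c("Cytb", "CR")`. The block end is
#'   always the CR.
#' @param cr_symbol symbol of the control region in `source`,
#'   default `"CR"`.
#' @return List of `tdrl_scenario` objects (possibly empty), each with
#'   `block`, `losses` (data.frame gene/copy), `loss_fragments` (number
#'   of contiguous lost fragments — the parsimony metadata),
#'   `intermediate` and `result` gene orders.
#' @export
enumerate_tdrl <- function(source, target, window = c("Cytb", "CR"),
                           cr_symbol = "CR") {
  sym <- source$symbols
  n <- length(sym)
  cr_pos <- which(sym == cr_symbol)
  if (length(cr_pos) != 1L)
    stop("source must contain exactly one '", cr_symbol, "'")
  loc <- locate_block(source, c(window[1], window[2]))
  rot <- rotate_order(source, loc$rot)   # window start at position 1
  wspan <- loc$span
  cr_in_w <- which(rot$symbols[wspan] == cr_symbol)
  if (!length(cr_in_w))
    stop("window must contain the control region")
  scenarios <- list()
  for (bstart in seq_len(cr_in_w)) {
    block <- c(rot$symbols[bstart], cr_symbol)
    dup_genes <- rot$symbols[bstart:cr_in_w]
    dup_non_cr <- dup_genes[dup_genes != cr_symbol]
    k <- length(dup_non_cr)
    intermediate <- apply_tdrl(source, block, list())
    loss_choices <- if (k == 0) list(integer(0)) else
      lapply(seq_len(2^k) - 1L, function(bits)
        as.integer(intToBits(bits)[seq_len(k)]) + 1L)
    for (choice in loss_choices) {
      losses <- if (k == 0) list() else
        lapply(seq_len(k), function(i) list(dup_non_cr[i], choice[i]))
      res <- apply_tdrl(source, block, losses)
      if (order_equal(res, target)) {
        loss_df <- if (k == 0)
          data.frame(gene = character(0), copy = integer(0))
        else data.frame(gene = dup_non_cr, copy = choice,
                        stringsAsFactors = FALSE)
        scenarios[[length(scenarios) + 1L]] <- structure(
          list(block = block,
               block_genes = dup_genes,
               losses = loss_df,
               loss_fragments = count_loss_fragments(dup_non_cr, choice,
                                                     length(dup_genes)),
               intermediate = intermediate,
               result = res),
          class = "tdrl_scenario")
      }
    }
  }
  blen <- vapply(scenarios, function(s) length(s$block_genes), 0L)
  scenarios[order(blen)]
}

# number of contiguous lost fragments in the tandem duplication
# (genes of copy 1 precede genes of copy 2 in the duplicated layout)
count_loss_fragments <- function(genes, choice, block_len) {
  if (!length(genes)) return(0L)
  # positions of the non-CR genes inside block copy 1 and copy 2
  pos1 <- match(genes, genes)               # order within the block
  lost_pos <- ifelse(choice == 1L, pos1, pos1 + block_len)
  lost_pos <- sort(lost_pos)
  sum(diff(c(-10L, lost_pos)) > 1L)
}

#' Label the duplication intermediate of a TDRL scenario
#'
#' @param scenario a `tdrl_scenario`.
#' @return List with `type` (the [classify_gene_order()] label of the
#'   intermediate, e.g. T1/T2/T3) and the intermediate `order`.
#' @export
scenario_intermediates <- function(scenario) {
  list(type = classify_gene_order(scenario$intermediate),
       order = scenario$intermediate)
}

#' @export
print.tdrl_scenario <- function(x, ...) {
  cat(sprintf("<TDRL> duplicate %s (%d genes); lose %s; %d fragment(s)\n",
              paste(x$block, collapse = ".."), length(x$block_genes),
              if (nrow(x$losses))
                paste(sprintf("%s(%d)", x$losses$gene, x$losses$copy),
                      collapse = " ") else "nothing",
              x$loss_fragments))
  invisible(x)
}

#' Serialise TDRL scenarios to JSON
#'
#' @param scenarios list of `tdrl_scenario` objects.
#' @param path optional output path.
#' @return JSON string (invisibly when written to file).
#' @export
tdrl_json <- function(scenarios, path = NULL) {
  payload <- lapply(scenarios, function(s) list(
    block = paste(s$block, collapse = ".."),
    block_genes = s$block_genes,
    losses = s$losses,
    loss_fragments = s$loss_fragments,
    intermediate_type = classify_gene_order(s$intermediate),
    intermediate = s$intermediate$labels,
    result = s$result$labels))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
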