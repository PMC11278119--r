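# Parsimony mapping of gene-order / repeat-presence traits on a
# supplied phylogeny, and the CR1/CR2 repeat-association test.

#' Parse a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that validates the result and
#' reports parse failures with the offending text.
#'
#' @param text Newick string, or a file path via `file`.
#' @param file optional path to a Newick file.
#' @return An `ape::phylo` tree (branch lengths preserved when present).
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  tr <- tryCatch(
    if (!is.null(file)) ape::read.tree(file) else ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed Newick: ",
         substr(if (is.null(text)) file else text, 1, 60))
  tr
}

#' Minimum-change ancestral states by generalized (Fitch) parsimony
#'
#' Two-pass parsimony for a discrete character on a rooted tree,
#' exact also at multifurcations (at a polytomy the node keeps the
#' states held by the largest number of children and adds one change
#' per child outside that set — Hartigan's generalisation, which
#' reduces to Fitch's intersection/union rule on binary nodes). The
#' down pass resolves ambiguity deterministically: a node takes its
#' parent's state when that state is in its set, otherwise the
#' lexicographically smallest member; changes are recorded on branches
#' where the resolved state switches.
#'
#' @param tree `ape::phylo` rooted tree.
#' @param tip_states named character vector, one state per tip label.
#' @param allow_missing drop tips without a state instead of erroring.
#' @return `trait_tree` object: list with `tree`, `tip_states`,
#'   `node_sets` (state sets per node), `node_states` (resolved),
#'   `changes` (data.frame parent/child/from/to, one row per inferred
#'   change), `n_changes` (the parsimony minimum).
#' @export
fitch_ancestral <- function(tree, tip_states, allow_missing = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing)) {
    if (!allow_missing)
      stop("missing tip state(s): ", paste(missing, collapse = ", "))
    tree <- ape::drop.tip(tree, missing)
  }
  extra <- setdiff(names(tip_states), tree$tip.label)
  if (length(extra))
    stop("tip_states names a tip not in the tree: ",
         paste(extra, collapse = ", "))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  total <- ntip + nnode
  sets <- vector("list", total)
  for (i in seq_len(ntip))
    sets[[i]] <- as.character(tip_states[[tree$tip.label[i]]])

  edge <- tree$edge
  children <- split(edge[, 2], edge[, 1])
  # up pass in postorder
  po <- ape::reorder.phylo(tree, "postorder")$edge
  n_changes <- 0L
  for (node in unique(po[, 1])) {
    kids <- children[[as.character(node)]]
    votes <- table(unlist(sets[kids]))
    K <- max(votes)
    sets[[node]] <- sort(names(votes)[votes == K])
    n_changes <- n_changes + (length(kids) - K)
  }
  # down pass
  root <- ntip + 1L
  states <- character(total)
  states[root] <- sort(sets[[root]])[1]
  pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]
  changes <- list()
  for (r in seq_len(nrow(pre))) {
    parent <- pre[r, 1]; child <- pre[r, 2]
    ps <- states[parent]
    states[child] <- if (ps %in% sets[[child]]) ps else sort(sets[[child]])[1]
    if (states[child] != ps) {
      changes[[length(changes) + 1L]] <- data.frame(
        parent = parent, child = child, from = ps, to = states[child],
        child_label = if (child <= ntip) tree$tip.label[child] else
          paste0("node", child),
        stringsAsFactors = FALSE)
    }
  }
  changes <- if (length(changes)) do.call(rbind, changes)
    else data.frame(parent = integer(0), child = integer(0),
                    from = character(0), to = character(0),
                    child_label = character(0), stringsAsFactors = FALSE)
  structure(list(tree = tree, tip_states = tip_states,
                 node_sets = sets, node_states = states,
                 changes = changes, n_changes = as.integer(n_changes)),
            class = "trait_tree")
}

#' @export
print.trait_tree <- function(x, ...) {
  cat(sprintf("<trait tree> %d tips, %d state change(s)\n",
              length(x$tree$tip.label), x$n_changes))
  if (nrow(x$changes))
    for (r in seq_len(nrow(x$changes)))
      cat(sprintf("  %s -> %s on branch to %s\n", x$changes$from[r],
                  x$changes$to[r], x$changes$child_label[r]))
  invisible(x)
}

#' Branches on which a state originates
#'
#' @param fit a `trait_tree` from [fitch_ancestral()].
#' @param state the derived state of interest.
#' @return The rows of `fit$changes` with `to == state`.
#' @export
origin_branches <- function(fit, state) {
  fit$changes[fit$changes$to == state, , drop = FALSE]
}

#' Write an annotated Newick with inferred node states
#'
#' Node comments `[&state=X]` are attached as node labels.
#'
#' @param fit a `trait_tree`.
#' @param path optional output path.
#' @return Newick string (invisibly when written to file).
#' @export
annotated_newick <- function(fit, path = NULL) {
  tr <- fit$tree
  ntip <- length(tr$tip.label)
  tr$node.label <- paste0("state_",
                          fit$node_states[(ntip + 1):(ntip + tr$Nnode)])
  txt <- ape::write.tree(tr)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by hypergeometric enumeration: the
#' probabilities of all tables with the observed margins that are no
#' more probable than the observed table (with a 1e-7 relative slack
#' for floating-point ties) are summed. Used to test the association
#' between tandem-repeat presence in CR1 and in CR2 across species.
#'
#' @param table 2x2 matrix of nonnegative integer counts, or the counts
#'   `a, b, c, d` row-wise.
#' @param a,b,c,d alternative scalar interface.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))  # 2/252
#' @export
fisher_exact <- function(table = NULL, a = NULL, b = NULL, c = NULL,
                         d = NULL) {
  if (is.null(table)) table <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  if (sum(table) == 0) stop("fisher_exact: all-zero table")
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ])
  c1 <- sum(table[, 1]); c2 <- sum(table[, 2])
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, c1, c2, r1)
  pobs <- stats::dhyper(table[1, 1], c1, c2, r1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

#' Read a tip-trait table
#'
#' TSV with columns `tip`, then one column per trait (e.g.
#' `order_type`, `cr1_repeat`, `cr2_repeat`).
#'
#' @param path TSV path.
#' @param trait column to extract; when NULL the full data.frame is
#'   returned.
#' @return Named character vector of tip states, or the data.frame.
#' @export
read_trait_table <- function(path, trait = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot("tip" %in% names(tab))
  if (is.null(trait)) return(tab)
  stopifnot(trait %in% names(tab))
  stats::setNames(as.character(tab[[trait]]), tab$tip)
}
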