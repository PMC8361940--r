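#' Serialize a tree to canonical Newick text
#'
#' Children of every node are ordered by their lexicographically smallest
#' descendant tip label and branch lengths are written with six decimal
#' places, so the output is bit-stable: any in-memory child permutation of
#' the same tree serializes identically. Internal node labels (e.g.
#' bootstrap supports) are emitted when present.
#'
#' @param tree An [ape::phylo] tree with branch lengths (rooted or
#'   unrooted; an unrooted tree has a basal multifurcation).
#' @return A single Newick string, terminated by `;`.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop("tree must have at least 2 leaves")
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  minlab <- min_desc_labels(tree)
  nlab <- tree$node.label

  render <- function(node) {
    e <- kids[[as.character(node)]]
    if (is.null(e)) return(tree$tip.label[node])
    ch <- tree$edge[e, 2L]
    ord <- order(minlab[ch], method = "radix")
    parts <- vapply(seq_along(ord), function(k) {
      i <- e[ord[k]]
      child <- tree$edge[i, 2L]
      len <- if (is.null(tree$edge.length)) NULL else tree$edge.length[i]
      paste0(render(child),
             if (!is.null(len)) sprintf(":%.6f", len) else "")
    }, character(1L))
    lab <- if (!is.null(nlab) && node > ntip) nlab[node - ntip] else ""
    if (is.na(lab)) lab <- ""
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  paste0(render(ntip + 1L), ";")
}

# lexicographically smallest descendant tip label per node (tips included)
min_desc_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  lab <- character(nn)
  lab[seq_len(ntip)] <- tree$tip.label
  # edges in ape cladewise order: process in reverse for post-order
  for (i in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
    if (!nzchar(lab[p]) || lab[ch] < lab[p]) lab[p] <-
        if (nzchar(lab[p])) min(lab[p], lab[ch]) else lab[ch]
  }
  lab
}

#' Parse Newick text into a tree
#'
#' Parenthesis balance is checked first: the character offset of the first
#' unmatched `(` or `)` is reported on error. Parsing proper is delegated
#' to [ape::read.tree()].
#'
#' @param text A Newick string.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1L]]
  stack <- integer(0L)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      if (length(stack) == 0L)
        stop("unbalanced ')' at character offset ", i)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack))
    stop("unbalanced '(' at character offset ", stack[1L])
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick text")
  tr
}
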