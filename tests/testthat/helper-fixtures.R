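# shared fixtures and independent oracles

# identity-style substitution matrix over the package alphabet
identity_matrix <- function(match = 1L, mismatch = 0L) {
  ab <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V", "X")
  m <- matrix(mismatch, 21L, 21L, dimnames = list(ab, ab))
  diag(m) <- match
  structure(m, class = c("score_matrix", class(m)))
}

# independent affine-gap oracle: memoized recursion over all global
# alignments, with gap costs charged on state transitions (a formulation
# deliberately different from the package's three-matrix DP)
oracle_align_score <- function(a, b, S, go, ge) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    if (i > length(A) && j > length(B)) return(0)
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i <= length(A) && j <= length(B))
      best <- max(best, S[A[i], B[j]] + rec(i + 1L, j + 1L, "m"))
    if (i <= length(A))
      best <- max(best, -(if (state == "x") ge else go) + rec(i + 1L, j, "x"))
    if (j <= length(B))
      best <- max(best, -(if (state == "y") ge else go) + rec(i, j + 1L, "y"))
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, "m")
}

# random peptide over a restricted alphabet
rand_pep <- function(len, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# random binary tree with branch lengths, as an ape phylo (used to build
# exactly additive distance matrices for the NJ oracle)
rand_blen_tree <- function(n_leaves, min_len = 0.1, max_len = 2) {
  t <- ape::rtree(n_leaves, rooted = FALSE,
                  tip.label = sprintf("t%02d", seq_len(n_leaves)))
  t$edge.length <- stats::runif(nrow(t$edge), min_len, max_len)
  t
}

# unrooted bipartition key set of a tree (via the package-independent
# ape::prop.part on the rooted representation)
tree_splits <- function(t) {
  tips <- sort(t$tip.label)
  pp <- ape::prop.part(t)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(idx) {
    side <- sort(labs[idx])
    other <- setdiff(tips, side)
    s <- if (tips[1L] %in% side) other else side
    paste(s, collapse = "|")
  }, character(1L))
  sort(unique(keys[nzchar(keys)]))
}

# random gap-free pocket fingerprint over given positions
rand_fp <- function(id, positions, gap_at = integer(0L)) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  sym <- sample(aa, length(positions), replace = TRUE)
  sym[match(gap_at, positions)] <- "-"
  pocket_fingerprint(id, sym, positions)
}

# minimal hand-written alignment fixture around the bundled reference:
# member rows are built by editing the reference string
ref_based_msa <- function(...) {
  ann <- chi_era_annotation()
  rows <- list(...)
  msa(c(ann$ref_id, names(rows)),
      c(ann$ref_seq, unlist(rows, use.names = FALSE)))
}
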