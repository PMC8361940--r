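#' Global pairwise alignment with affine gap costs
#'
#' Needleman-Wunsch-Gotoh alignment of two residue strings. A gap of
#' length L costs `gap_open + (L - 1) * gap_extend`; terminal gaps are
#' penalized (true global alignment). Traceback is deterministic with tie
#' preference diagonal > up > left, so the returned alignment is unique.
#'
#' @param a,b Non-empty residue strings.
#' @param matrix A `score_matrix` (default [blosum62()]).
#' @param gap_open,gap_extend Non-negative gap penalties,
#'   `gap_extend <= gap_open`.
#' @return A list with `score`, and the two aligned strings `a_aln`,
#'   `b_aln` (gap symbol `-`), which degap back to the inputs.
#' @export
global_align <- function(a, b, matrix = blosum62(), gap_open = 11,
                         gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  stopifnot(gap_open >= 0, gap_extend >= 0, gap_extend <= gap_open)
  ca <- strsplit(toupper(a), "")[[1L]]
  cb <- strsplit(toupper(b), "")[[1L]]
  pa <- one_hot_profile(ca, matrix)
  pb <- one_hot_profile(cb, matrix)
  res <- cpp_profile_align(pa, pb, unclass(matrix) * 1.0, 1, 1,
                           gap_open, gap_extend)
  list(score = res$score,
       a_aln = paste(ifelse(is.na(res$a_cols), GAP, ca[res$a_cols]),
                     collapse = ""),
       b_aln = paste(ifelse(is.na(res$b_cols), GAP, cb[res$b_cols]),
                     collapse = ""))
}

one_hot_profile <- function(chars, matrix) {
  K <- nrow(matrix)
  idx <- encode_residues(chars, matrix)
  p <- matrix(0, nrow = K + 1L, ncol = length(chars))
  p[cbind(idx, seq_along(chars))] <- 1
  p
}

#' Construct a multiple alignment container
#'
#' @param ids Unique row ids.
#' @param aln Aligned strings of identical length (gap symbol `-`).
#' @return An `msa` object.
#' @export
msa <- function(ids, aln) {
  stopifnot(length(ids) == length(aln), !anyDuplicated(ids))
  w <- unique(nchar(aln))
  if (length(w) != 1L) stop("aligned rows have differing lengths")
  m <- structure(list(ids = as.character(ids), aln = as.character(aln),
                      ncol = w), class = "msa")
  names(m$aln) <- m$ids
  m
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", length(x$ids), "sequences x", x$ncol, "columns\n")
  invisible(x)
}

#' @export
as.matrix.msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$aln, ""))
  rownames(m) <- x$ids
  m
}

#' Progressive multiple sequence alignment
#'
#' Classic progressive scheme: pairwise global alignments give p-distance
#' estimates, a neighbor-joining guide tree is built from them
#' (midpoint-rooted, children in canonical order), and profiles are merged
#' from the leaves to the root with average-of-pairs column scoring under
#' the same affine gap model. With two sequences the result equals
#' [global_align()]. Row order follows the input order.
#'
#' @param records A `seq_records` data frame (at least two rows, unique ids).
#' @inheritParams global_align
#' @return An `msa` object; every row degaps to its input residues and no
#'   column is all-gap.
#' @export
build_msa <- function(records, matrix = blosum62(), gap_open = 11,
                      gap_extend = 1) {
  n <- nrow(records)
  if (is.null(n) || n < 2L) stop("need at least 2 sequences to align")
  if (anyDuplicated(records$id))
    stop("duplicate sequence id '",
         records$id[duplicated(records$id)][1L], "'")
  ids <- records$id
  seqs <- records$residues
  chars <- strsplit(toupper(seqs), "")
  profiles <- lapply(chars, one_hot_profile, matrix = matrix)
  S <- unclass(matrix) * 1.0

  if (n == 2L) {
    pw <- global_align(seqs[1L], seqs[2L], matrix, gap_open, gap_extend)
    return(msa(ids, c(pw$a_aln, pw$b_aln)))
  }

  # guide distances: fraction of non-identical pairwise alignment columns
  # (indel-aware, so members carrying long insertions join the guide tree
  # late and their insertions stay contiguous gap blocks in the merges)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    pw <- cpp_profile_align(profiles[[i]], profiles[[j]], S, 1, 1,
                            gap_open, gap_extend)
    both <- !is.na(pw$a_cols) & !is.na(pw$b_cols)
    matches <- sum(chars[[i]][pw$a_cols[both]] == chars[[j]][pw$b_cols[both]])
    d[i, j] <- d[j, i] <- 1 - matches / length(pw$a_cols)
  }
  guide <- midpoint_root(nj_tree(dist_matrix(d)))
  guide <- ape::reorder.phylo(guide, "cladewise")

  kids <- split(seq_len(nrow(guide$edge)), guide$edge[, 1L])
  minlab <- min_desc_labels(guide)
  ntip <- length(guide$tip.label)

  # returns list(rows = character row ids, aln = character matrix rows)
  merge_node <- function(node) {
    e <- kids[[as.character(node)]]
    if (is.null(e)) {
      id <- guide$tip.label[node]
      return(list(rows = id, cols = matrix(chars[[match(id, ids)]], nrow = 1L)))
    }
    ch <- guide$edge[e, 2L]
    ch <- ch[order(minlab[ch], method = "radix")]
    acc <- merge_node(ch[1L])
    for (c2 in ch[-1L]) {
      nxt <- merge_node(c2)
      acc <- merge_profiles(acc, nxt, S, matrix, gap_open, gap_extend)
    }
    acc
  }
  res <- merge_node(ntip + 1L)
  aln <- apply(res$cols, 1L, paste, collapse = "")
  names(aln) <- res$rows
  msa(ids, unname(aln[ids]))
}

merge_profiles <- function(a, b, S, matrix, gap_open, gap_extend) {
  pa <- counts_profile(a$cols, matrix)
  pb <- counts_profile(b$cols, matrix)
  pw <- cpp_profile_align(pa, pb, S, nrow(a$cols), nrow(b$cols),
                          gap_open, gap_extend)
  L <- length(pw$a_cols)
  out <- matrix(GAP, nrow = nrow(a$cols) + nrow(b$cols), ncol = L)
  ia <- seq_len(nrow(a$cols))
  keep <- !is.na(pw$a_cols)
  out[ia, keep] <- a$cols[, pw$a_cols[keep], drop = FALSE]
  keep <- !is.na(pw$b_cols)
  out[nrow(a$cols) + seq_len(nrow(b$cols)), keep] <-
    b$cols[, pw$b_cols[keep], drop = FALSE]
  list(rows = c(a$rows, b$rows), cols = out)
}

counts_profile <- function(cols, matrix) {
  K <- nrow(matrix)
  p <- matrix(0, nrow = K + 1L, ncol = ncol(cols))
  for (r in seq_len(nrow(cols))) {
    idx <- ifelse(cols[r, ] == GAP, K + 1L,
                  match(cols[r, ], rownames(matrix)))
    p[cbind(idx, seq_len(ncol(cols)))] <-
      p[cbind(idx, seq_len(ncol(cols)))] + 1
  }
  p
}

#' Write / read an alignment as FASTA-with-gaps
#'
#' @param x An `msa` object.
#' @param path File path.
#' @return `write_msa`: `path` invisibly; `read_msa`: an `msa`.
#' @export
write_msa <- function(x, path) {
  df <- data.frame(id = x$ids, description = "", residues = unname(x$aln),
                   stringsAsFactors = FALSE)
  out <- character(0L)
  for (k in seq_len(nrow(df))) {
    s <- df$residues[k]
    starts <- seq.int(1L, nchar(s), by = 60L)
    out <- c(out, paste0(">", df$id[k]),
             substring(s, starts, pmin(starts + 59L, nchar(s))))
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_msa
#' @export
read_msa <- function(path) {
  rec <- read_fasta(path, keep_gaps = TRUE)
  if (nrow(rec) < 2L) stop("alignment must contain at least 2 rows")
  msa(rec$id, rec$residues)
}

#' Corrected protein distance matrix from an alignment
#'
#' For every pair of rows, `p` is the mismatch fraction over columns where
#' both rows carry a residue. Model `"p"` returns `p` itself; `"poisson"`
#' applies the Poisson multiple-hit correction `-ln(1 - p)`.
#'
#' @param msa An `msa` object with at least 2 rows.
#' @param model `"p"` or `"poisson"`.
#' @return A `dist_matrix`: symmetric numeric matrix with zero diagonal and
#'   the row ids as labels.
#' @export
distance_matrix <- function(msa, model = c("poisson", "p")) {
  model <- match.arg(model)
  m <- as.matrix(msa)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 rows")
  d <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    both <- m[i, ] != GAP & m[j, ] != GAP
    if (!any(both))
      stop("no compared columns between '", msa$ids[i], "' and '",
           msa$ids[j], "'")
    p <- sum(m[i, both] != m[j, both]) / sum(both)
    if (model == "poisson") {
      if (p >= 1)
        stop("saturated distance (p = 1) between '", msa$ids[i], "' and '",
             msa$ids[j], "' under poisson correction")
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  dist_matrix(d)
}

#' Construct a labelled distance matrix
#'
#' @param d A symmetric non-negative numeric matrix with zero diagonal and
#'   dimnames.
#' @return A `dist_matrix` object.
#' @export
dist_matrix <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), !is.null(rownames(d)))
  if (any(!is.finite(d)) || any(d < 0)) stop("distances must be finite and >= 0")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  structure(d, class = c("dist_matrix", class(d)))
}
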