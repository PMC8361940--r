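#' Read a substitution matrix in NCBI text layout
#'
#' Parses the whitespace-separated square matrix layout used by the NCBI
#' tools (`#` comment lines, a header row of symbols, then one labelled row
#' per symbol). The matrix must be square and symmetric.
#'
#' @param path Path to a matrix file.
#' @return A `score_matrix`: an integer matrix with symbol dimnames.
#' @export
read_score_matrix <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("matrix file has no data: ", path)
  alphabet <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  lab <- vapply(rows, `[`, character(1L), 1L)
  m <- do.call(rbind, lapply(rows, function(r) as.integer(r[-1L])))
  if (ncol(m) != length(alphabet) || nrow(m) != length(alphabet) ||
      !identical(lab, alphabet))
    stop("matrix is not square over its header alphabet: ", path)
  dimnames(m) <- list(alphabet, alphabet)
  if (!isTRUE(all.equal(m, t(m))))
    stop("substitution matrix is not symmetric: ", path)
  structure(m, class = c("score_matrix", class(m)))
}

.blosum62_cache <- new.env(parent = emptyenv())

#' The bundled BLOSUM62 substitution matrix
#'
#' Half-bit BLOSUM62 scores over the 20 standard amino acids plus `X`
#' (unknown residue, scored -1 against everything including itself).
#'
#' @return A `score_matrix`.
#' @export
blosum62 <- function() {
  if (is.null(.blosum62_cache$m))
    .blosum62_cache$m <- read_score_matrix(
      system.file("extdata", "BLOSUM62.txt", package = "ssfe", mustWork = TRUE))
  .blosum62_cache$m
}

# encode residue characters as 1-based indices into the matrix alphabet;
# errors name the first offending symbol
encode_residues <- function(chars, matrix) {
  idx <- match(chars, rownames(matrix))
  if (anyNA(idx))
    stop("symbol not in substitution matrix alphabet: ",
         chars[which(is.na(idx))[1L]])
  idx
}

score_pair <- function(a, b, matrix) {
  matrix[cbind(encode_residues(a, matrix), encode_residues(b, matrix))]
}
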