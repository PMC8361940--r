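#' Read a minimal PDB structure
#'
#' Fixed-column parser for PDB coordinate records, sufficient for
#' ligand-contact geometry: `ATOM` records populate the polymer residues,
#' `HETATM` records the ligands. Only the first model is read (parsing
#' stops at `ENDMDL`) and alternate locations are resolved by keeping the
#' first record seen for each atom. Residue numbers must be strictly
#' increasing within a chain.
#'
#' @param path Path to a PDB file.
#' @return A `structure_model`: a list with data frames `residues` and
#'   `ligands`, each with columns `chain`, `resno`, `resname`, `atom`,
#'   `element`, `x`, `y`, `z`.
#' @export
read_pdb_minimal <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]
  rec <- substr(lines, 1L, 6L)
  keep <- which(rec %in% c("ATOM  ", "HETATM") | trimws(rec) %in% c("ATOM", "HETATM"))
  if (length(keep) == 0L) stop("no coordinate records in ", path)

  parse_field <- function(txt, ln, what) {
    v <- suppressWarnings(as.numeric(txt))
    if (is.na(v) || !is.finite(v))
      stop("unparseable ", what, " field '", trimws(txt), "' at line ", ln,
           " of ", path)
    v
  }
  n <- length(keep)
  chain <- resname <- atom <- altloc <- element <- character(n)
  resno <- integer(n)
  x <- y <- z <- numeric(n)
  het <- logical(n)
  for (k in seq_len(n)) {
    ln <- keep[k]
    l <- lines[ln]
    het[k] <- startsWith(l, "HETATM")
    atom[k] <- trimws(substr(l, 13L, 16L))
    altloc[k] <- substr(l, 17L, 17L)
    resname[k] <- trimws(substr(l, 18L, 20L))
    chain[k] <- substr(l, 22L, 22L)
    rn <- suppressWarnings(as.integer(trimws(substr(l, 23L, 26L))))
    if (is.na(rn)) stop("unparseable residue number at line ", ln, " of ", path)
    resno[k] <- rn
    x[k] <- parse_field(substr(l, 31L, 38L), ln, "x")
    y[k] <- parse_field(substr(l, 39L, 46L), ln, "y")
    z[k] <- parse_field(substr(l, 47L, 54L), ln, "z")
    element[k] <- toupper(trimws(substr(l, 77L, 78L)))
  }
  # infer missing elements from the atom name (digits stripped, first letter)
  miss <- !nzchar(element)
  element[miss] <- substr(gsub("[0-9']", "", atom[miss]), 1L, 1L)

  # first altloc wins, per atom identity
  key <- paste(het, chain, resno, atom, sep = "\r")
  first <- !duplicated(key)
  df <- data.frame(chain = chain, resno = resno, resname = resname,
                   atom = atom, element = element, x = x, y = y, z = z,
                   stringsAsFactors = FALSE)[first, , drop = FALSE]
  het <- het[first]
  residues <- df[!het, , drop = FALSE]
  ligands <- df[het, , drop = FALSE]
  rownames(residues) <- rownames(ligands) <- NULL

  for (ch in unique(residues$chain)) {
    rn <- residues$resno[residues$chain == ch]
    runs <- rle(rn)$values
    if (any(diff(runs) <= 0L))
      stop("residue numbers not strictly increasing in chain '", ch,
           "' of ", path)
  }
  structure(list(residues = residues, ligands = ligands),
            class = "structure_model")
}

#' Write a minimal PDB file
#'
#' Emits fixed-column `ATOM`/`HETATM` coordinate records only; the
#' complement of [read_pdb_minimal()], used mainly to materialize toy
#' structures from [make_toy_structure()].
#'
#' @param s A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_minimal <- function(s, path) {
  fmt <- function(df, rectype, serial0) {
    if (nrow(df) == 0L) return(character(0L))
    sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            rectype, serial0 + seq_len(nrow(df)), substr(df$atom, 1L, 4L),
            substr(df$resname, 1L, 3L), df$chain, df$resno,
            df$x, df$y, df$z, df$element)
  }
  out <- c(fmt(s$residues, "ATOM", 0L),
           fmt(s$ligands, "HETATM", nrow(s$residues)),
           "END")
  writeLines(out, path)
  invisible(path)
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", length(unique(paste(x$residues$chain, x$residues$resno))),
      "polymer residues,",
      length(unique(paste(x$ligands$chain, x$ligands$resno, x$ligands$resname))),
      "ligand(s)\n")
  invisible(x)
}
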