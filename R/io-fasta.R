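#' Read amino-acid sequences from a FASTA file
#'
#' Strict reader for protein FASTA. Residues are upper-cased and
#' concatenated across wrapped lines; gap characters (`-` and `.`) are
#' stripped, so pre-aligned input is accepted and re-alignable. Sequence
#' ids (the first whitespace-delimited token of the header) must be unique
#' within the file; any character outside the 20 amino-acid letters plus
#' `X` is rejected with its line number.
#'
#' @param path Path to a FASTA file.
#' @param keep_gaps Keep gap columns (used for alignment interchange, see
#'   [read_msa()]).
#' @return A data frame of class `seq_records` with columns `id`,
#'   `description` and `residues`, one row per record in file order. An
#'   empty file yields zero rows.
#' @export
read_fasta <- function(path, keep_gaps = FALSE) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) {
    if (any(nzchar(trimws(lines))))
      stop("not a FASTA file (no '>' header): ", path)
    return(empty_records())
  }
  if (any(nzchar(trimws(lines[seq_len(hdr[1L] - 1L)]))))
    stop("sequence data before first header in ", path)

  ids <- desc <- res <- character(length(hdr))
  bounds <- c(hdr, length(lines) + 1L)
  allowed <- c(AA_LETTERS, "X", if (keep_gaps) GAP)
  for (k in seq_along(hdr)) {
    h <- sub("^>", "", lines[hdr[k]])
    ids[k] <- sub("\\s.*$", "", h)
    desc[k] <- if (grepl("\\s", h)) sub("^\\S+\\s+", "", h) else ""
    body_lines <- seq.int(hdr[k] + 1L, bounds[k + 1L] - 1L, length.out =
                            max(0L, bounds[k + 1L] - hdr[k] - 1L))
    seq <- ""
    for (ln in body_lines) {
      s <- toupper(gsub("\\s", "", lines[ln]))
      s <- gsub("\\.", "-", s)
      bad <- setdiff(strsplit(s, "")[[1L]], c(allowed, GAP))
      if (length(bad))
        stop("invalid residue character '", bad[1L], "' at line ", ln,
             " of ", path)
      if (!keep_gaps) s <- gsub("-", "", s, fixed = TRUE)
      seq <- paste0(seq, s)
    }
    if (!nzchar(seq))
      stop("record '", ids[k], "' has an empty sequence in ", path)
    res[k] <- seq
  }
  if (anyDuplicated(ids))
    stop("duplicate sequence id '", ids[duplicated(ids)][1L], "' in ", path)
  if (!all(nzchar(ids))) stop("empty sequence id in ", path)
  if (keep_gaps) {
    if (any(grepl("\\s", ids))) stop("sequence ids must not contain whitespace")
    return(structure(data.frame(id = ids, description = desc, residues = res,
                                stringsAsFactors = FALSE),
                     class = c("seq_records", "data.frame")))
  }
  seq_records(ids, res, desc)
}

#' Construct a set of sequence records
#'
#' @param id,residues,description Character vectors of equal length;
#'   `residues` are upper-cased on construction.
#' @return A `seq_records` data frame.
#' @export
seq_records <- function(id, residues, description = "") {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (anyDuplicated(id)) stop("duplicate sequence id '",
                              id[duplicated(id)][1L], "'")
  if (any(grepl("\\s", id))) stop("sequence ids must not contain whitespace")
  if (any(!nzchar(residues))) stop("empty residue string")
  bad <- setdiff(unlist(strsplit(residues, "")), c(AA_LETTERS, "X"))
  if (length(bad)) stop("invalid residue character '", bad[1L], "'")
  structure(data.frame(id = id, description = rep_len(description, length(id)),
                       residues = residues, stringsAsFactors = FALSE),
            class = c("seq_records", "data.frame"))
}

empty_records <- function() {
  structure(data.frame(id = character(), description = character(),
                       residues = character(), stringsAsFactors = FALSE),
            class = c("seq_records", "data.frame"))
}

#' Write sequences to FASTA
#'
#' Records are written in order, wrapped at 60 columns.
#'
#' @param records A `seq_records` data frame (gaps allowed for alignments).
#' @param path Output path.
#' @param width Wrap width in columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  out <- character(0L)
  for (k in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$description[k]))
      paste0(">", records$id[k], " ", records$description[k])
    else paste0(">", records$id[k])
    s <- records$residues[k]
    starts <- seq.int(1L, nchar(s), by = width)
    out <- c(out, hdr, substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }
  writeLines(out, path)
  invisible(path)
}
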