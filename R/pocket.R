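#' Map reference positions onto a homolog through an alignment
#'
#' Walks the alignment columns: wherever the reference row carries a
#' residue, the reference position maps to the homolog's residue position
#' in that column, or to `NA` ("unaligned") when the homolog row has a gap
#' there. The mapping is strictly increasing over mapped positions.
#'
#' @param msa An `msa` containing both ids.
#' @param ref_id Reference row id.
#' @param member_id Homolog row id.
#' @return A `position_map`: integer vector indexed by reference position,
#'   `NA` for unaligned positions, with the alignment column of each
#'   reference position in attribute `ref_col`.
#' @export
build_position_map <- function(msa, ref_id, member_id) {
  for (id in c(ref_id, member_id))
    if (!id %in% msa$ids) stop("id '", id, "' not in alignment")
  ref <- strsplit(msa$aln[[ref_id]], "")[[1L]]
  mem <- strsplit(msa$aln[[member_id]], "")[[1L]]
  ref_cols <- which(ref != GAP)
  mem_pos <- cumsum(mem != GAP)
  map <- ifelse(mem[ref_cols] != GAP, mem_pos[ref_cols], NA_integer_)
  structure(as.integer(map), ref_id = ref_id, member_id = member_id,
            ref_col = ref_cols, class = "position_map")
}

#' Extract a homolog's pocket fingerprint in reference numbering
#'
#' The fingerprint is the ordered residue symbols the homolog presents at
#' the annotated pocket positions; `-` marks a pocket position that is
#' unaligned (deleted) in the homolog.
#'
#' @param msa An `msa` containing the reference and the member.
#' @param annotation A `ref_annotation` (its `ref_id` names the reference
#'   row).
#' @param member_id Homolog row id.
#' @return A `pocket_fingerprint`.
#' @export
extract_fingerprint <- function(msa, annotation, member_id) {
  map <- build_position_map(msa, annotation$ref_id, member_id)
  mem <- gsub(GAP, "", msa$aln[[member_id]], fixed = TRUE)
  mem_chars <- strsplit(mem, "")[[1L]]
  pos <- annotation$pocket$position
  sym <- ifelse(is.na(map[pos]), GAP, mem_chars[ifelse(is.na(map[pos]), 1L,
                                                       map[pos])])
  pocket_fingerprint(member_id, sym, pos)
}

#' Construct a pocket fingerprint
#'
#' @param id Member id.
#' @param symbols Residue symbols (or `-`), one per pocket position.
#' @param positions Reference positions, strictly increasing.
#' @return A `pocket_fingerprint`: list with `id`, `symbols` (named by
#'   position) and `positions`.
#' @export
pocket_fingerprint <- function(id, symbols, positions) {
  stopifnot(length(symbols) == length(positions),
            !is.unsorted(positions, strictly = TRUE))
  symbols <- toupper(as.character(symbols))
  names(symbols) <- positions
  structure(list(id = id, symbols = symbols,
                 positions = as.integer(positions)),
            class = "pocket_fingerprint")
}

#' @export
print.pocket_fingerprint <- function(x, ...) {
  cat("pocket_fingerprint", x$id, ":", paste(x$symbols, collapse = ""), "\n")
  invisible(x)
}

#' @export
format.pocket_fingerprint <- function(x, ...) paste(x$symbols, collapse = "")

#' The reference's own fingerprint implied by an annotation
#'
#' @param annotation A `ref_annotation`.
#' @return A `pocket_fingerprint` of the annotated reference residues.
#' @export
reference_fingerprint <- function(annotation) {
  pocket_fingerprint(annotation$ref_id, annotation$pocket$residue,
                     annotation$pocket$position)
}

#' Substitution-score distance between two pocket fingerprints
#'
#' Per slot, the cost is `[s(a,a) + s(b,b)]/2 - s(a,b)` (zero for
#' identical symbols, non-negative for any matrix with
#' `s(a,a) + s(b,b) >= 2 s(a,b)`); a slot where exactly one side is `-`
#' costs `gap_penalty`, and a both-gap slot costs nothing (absence of
#' evidence is not counted twice). The total is a symmetric premetric.
#'
#' @param f1,f2 `pocket_fingerprint`s over the same annotation positions.
#' @param matrix A `score_matrix`.
#' @param gap_penalty Cost of a residue-vs-gap slot.
#' @return A non-negative number.
#' @export
fingerprint_distance <- function(f1, f2, matrix = blosum62(),
                                 gap_penalty = 8) {
  if (length(f1$symbols) != length(f2$symbols) ||
      !identical(f1$positions, f2$positions))
    stop("fingerprints are over different pocket annotations")
  a <- unname(f1$symbols); b <- unname(f2$symbols)
  ga <- a == GAP; gb <- b == GAP
  d <- sum(gap_penalty * (xor(ga, gb)))
  both <- !ga & !gb
  if (any(both)) {
    sa <- score_pair(a[both], a[both], matrix)
    sb <- score_pair(b[both], b[both], matrix)
    sab <- score_pair(a[both], b[both], matrix)
    d <- d + sum((sa + sb) / 2 - sab)
  }
  d
}

#' Detect domain disruption from alignment geometry
#'
#' For each annotated domain span, measures the longest run of homolog
#' residues inserted between consecutive mapped reference positions inside
#' the span, and the count of unaligned (deleted) reference positions in
#' the span. The member is flagged disrupted when any span exceeds either
#' threshold - the sequence signature of ordered regions being replaced by
#' long flexible loops.
#'
#' @param msa An `msa` containing reference and member.
#' @param annotation A `ref_annotation` with domain spans.
#' @param member_id Homolog row id.
#' @param max_insert Maximum tolerated insertion length (residues).
#' @param max_unaligned Maximum tolerated unaligned reference positions
#'   per span; `NULL` means 25% of the span length, rounded down.
#' @return A `disruption_report`: data frame with one row per domain
#'   (`domain`, `max_insert_run`, `unaligned`, `span_disrupted`) and the
#'   overall flag in attribute `disrupted`.
#' @export
detect_disruption <- function(msa, annotation, member_id, max_insert = 10L,
                              max_unaligned = NULL) {
  if (nrow(annotation$domains) == 0L) stop("annotation has no domain spans")
  map <- build_position_map(msa, annotation$ref_id, member_id)
  mem <- strsplit(msa$aln[[member_id]], "")[[1L]]
  ref_col <- attr(map, "ref_col")

  rows <- lapply(seq_len(nrow(annotation$domains)), function(k) {
    span <- annotation$domains[k, ]
    pos <- seq.int(span$start, span$end)
    unaligned <- sum(is.na(map[pos]))
    # homolog residues strictly between consecutive mapped ref positions
    mapped <- pos[!is.na(map[pos])]
    max_run <- 0L
    if (length(mapped) >= 2L) {
      for (i in seq_len(length(mapped) - 1L)) {
        c1 <- ref_col[mapped[i]]; c2 <- ref_col[mapped[i + 1L]]
        if (c2 > c1 + 1L) {
          run <- sum(mem[seq.int(c1 + 1L, c2 - 1L)] != GAP)
          if (run > max_run) max_run <- run
        }
      }
    }
    lim <- if (is.null(max_unaligned)) floor(0.25 * length(pos))
           else max_unaligned
    data.frame(domain = span$label, max_insert_run = max_run,
               unaligned = unaligned,
               span_disrupted = max_run > max_insert | unaligned > lim,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, member_id = member_id, disrupted = any(out$span_disrupted),
            class = c("disruption_report", "data.frame"))
}

#' Is a member disrupted?
#'
#' @param report A `disruption_report`.
#' @return Logical flag.
#' @export
is_disrupted <- function(report) isTRUE(attr(report, "disrupted"))

#' Pocket positions from a structure by ligand contact
#'
#' Returns the polymer residue numbers having at least one heavy atom
#' within `cutoff` (inclusive) of any heavy atom of the named ligand.
#' Hydrogens are excluded by element.
#'
#' @param s A `structure_model`.
#' @param ligand Ligand residue name; the structure must contain exactly
#'   one ligand with this name.
#' @param cutoff Contact cutoff in Angstrom.
#' @return Sorted integer vector of residue numbers (possibly empty).
#' @export
pocket_from_structure <- function(s, ligand, cutoff = 4.5) {
  lig <- s$ligands[s$ligands$resname == ligand, , drop = FALSE]
  if (nrow(lig) == 0L) stop("no ligand named '", ligand, "' in structure")
  inst <- unique(lig[, c("chain", "resno")])
  if (nrow(inst) > 1L)
    stop("multiple ligands named '", ligand, "': ",
         paste(paste0(inst$chain, inst$resno), collapse = ", "))
  lig <- lig[lig$element != "H", , drop = FALSE]
  res <- s$residues[s$residues$element != "H", , drop = FALSE]
  if (nrow(res) == 0L || nrow(lig) == 0L) return(integer(0L))
  lx <- as.matrix(lig[, c("x", "y", "z")])
  rx <- as.matrix(res[, c("x", "y", "z")])
  hit <- vapply(seq_len(nrow(rx)), function(i) {
    d2 <- (lx[, 1L] - rx[i, 1L])^2 + (lx[, 2L] - rx[i, 2L])^2 +
      (lx[, 3L] - rx[i, 3L])^2
    any(d2 <= cutoff^2 + 1e-9)
  }, logical(1L))
  sort(unique(res$resno[hit]))
}

#' Write pocket fingerprints as TSV
#'
#' One row per member; the header row carries the reference positions.
#'
#' @param fps List of `pocket_fingerprint`s over the same annotation.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path) {
  stopifnot(length(fps) >= 1L)
  pos <- fps[[1L]]$positions
  m <- do.call(rbind, lapply(fps, function(f) {
    stopifnot(identical(f$positions, pos))
    f$symbols
  }))
  df <- data.frame(member_id = vapply(fps, `[[`, character(1L), "id"), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("member_id", paste0("p", pos))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pocket fingerprints from TSV
#'
#' @param path A TSV written by [write_fingerprints()].
#' @return A list of `pocket_fingerprint`s.
#' @export
read_fingerprints <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  pos <- as.integer(sub("^p", "", colnames(df)[-1L]))
  lapply(seq_len(nrow(df)), function(i)
    pocket_fingerprint(df$member_id[i], unlist(df[i, -1L], use.names = FALSE),
                       pos))
}
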