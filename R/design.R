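#' Select a diversity-maximizing representative panel
#'
#' Greedy maximin selection over pocket fingerprints, emulating the choice
#' of sequences with representative substrate-binding pockets: the panel
#' is seeded with the member closest to the reference fingerprint, then
#' repeatedly extended with the member maximizing its minimum distance to
#' the panel, subject to the constraint that no pocket-type cluster
#' contributes a second representative until every cluster is covered.
#' Distance ties prefer members from clades not yet represented, then the
#' lexicographically smallest id, so the panel is deterministic.
#'
#' @param fps List of candidate `pocket_fingerprint`s.
#' @param clusters Output of [cluster_pocket_types()] over (a superset of)
#'   the candidates.
#' @param ref_fp The reference `pocket_fingerprint` used for seeding.
#' @param k Panel size (1 <= k <= number of candidates).
#' @param partition Optional `clade_partition` used for tie preference.
#' @param matrix,gap_penalty Passed to [fingerprint_distance()].
#' @return Character vector of `k` member ids.
#' @export
select_representatives <- function(fps, clusters, ref_fp, k,
                                   partition = NULL, matrix = blosum62(),
                                   gap_penalty = 8) {
  ids <- vapply(fps, `[[`, character(1L), "id")
  stopifnot(k >= 1L)
  if (k > length(fps))
    stop("k = ", k, " exceeds the number of candidate members (",
         length(fps), ")")
  cluster_of <- stats::setNames(
    rep(vapply(clusters, `[[`, integer(1L), "cluster_id"),
        vapply(clusters, function(cl) length(cl$members), integer(1L))),
    unlist(lapply(clusters, `[[`, "members")))[ids]
  clade_of <- if (is.null(partition)) rep(NA_integer_, length(ids))
              else partition$clade_id[match(ids, partition$member_id)]

  dref <- vapply(fps, fingerprint_distance, numeric(1L), f2 = ref_fp,
                 matrix = matrix, gap_penalty = gap_penalty)
  pick_tie <- function(cand_idx, chosen_idx) {
    # prefer covering a new clade, then smallest id
    new_clade <- !(clade_of[cand_idx] %in% clade_of[chosen_idx]) &
      !is.na(clade_of[cand_idx])
    if (any(new_clade)) cand_idx <- cand_idx[new_clade]
    cand_idx[order(ids[cand_idx], method = "radix")[1L]]
  }

  seed_cand <- which(dref == min(dref))
  chosen <- seed_cand[order(ids[seed_cand], method = "radix")[1L]]

  D <- matrix(0, length(fps), length(fps))
  if (length(fps) > 1L)
    for (i in seq_len(length(fps) - 1L)) for (j in seq.int(i + 1L, length(fps)))
      D[i, j] <- D[j, i] <- fingerprint_distance(fps[[i]], fps[[j]], matrix,
                                                 gap_penalty)
  while (length(chosen) < k) {
    remaining <- setdiff(seq_along(fps), chosen)
    covered <- unique(cluster_of[chosen])
    all_covered <- all(unique(cluster_of) %in% covered)
    if (!all_covered) {
      fresh <- remaining[!(cluster_of[remaining] %in% covered)]
      if (length(fresh)) remaining <- fresh
    }
    mind <- vapply(remaining, function(i) min(D[i, chosen]), numeric(1L))
    best <- remaining[mind == max(mind)]
    chosen <- c(chosen, pick_tie(best, chosen))
  }
  ids[chosen]
}

#' Propose pocket-transplant mutations
#'
#' Builds the mutation set converting the scaffold's pocket fingerprint
#' into the target's: one substitution per slot where the symbols differ,
#' named in reference numbering (e.g. `D79P`) regardless of the
#' scaffold's own numbering. Slots where the target is unresolved (`-`)
#' are skipped and reported.
#'
#' @param scaffold_fp Gap-free `pocket_fingerprint` of the scaffold.
#' @param target_fp Target `pocket_fingerprint` over the same annotation.
#' @return A `mutation_set`: list with `scaffold`, `source`, `mutations`
#'   (data frame `position`, `from`, `to`, `label`) and `unresolvable`
#'   (integer positions).
#' @export
propose_mutations <- function(scaffold_fp, target_fp) {
  if (!identical(scaffold_fp$positions, target_fp$positions))
    stop("fingerprints are over different pocket annotations")
  if (any(scaffold_fp$symbols == GAP))
    stop("scaffold fingerprint must be gap-free")
  s <- unname(scaffold_fp$symbols); t <- unname(target_fp$symbols)
  unres <- scaffold_fp$positions[t == GAP]
  sel <- which(s != t & t != GAP)
  mut <- data.frame(position = scaffold_fp$positions[sel], from = s[sel],
                    to = t[sel],
                    label = paste0(s[sel], scaffold_fp$positions[sel], t[sel]),
                    stringsAsFactors = FALSE)
  structure(list(scaffold = scaffold_fp$id, source = target_fp$id,
                 mutations = mut, unresolvable = unres),
            class = "mutation_set")
}

#' @export
print.mutation_set <- function(x, ...) {
  cat("mutation_set", x$scaffold, "->", x$source, ":",
      if (nrow(x$mutations)) paste(x$mutations$label, collapse = ", ")
      else "(none)",
      if (length(x$unresolvable))
        paste0(" [unresolvable: ", paste(x$unresolvable, collapse = ","), "]")
      else "", "\n")
  invisible(x)
}

#' Apply a mutation set to a scaffold fingerprint
#'
#' @param scaffold_fp A `pocket_fingerprint`; every mutation's from-symbol
#'   must match it at the mutated position.
#' @param ms A `mutation_set`.
#' @return The mutated `pocket_fingerprint` (id suffixed with `_mut`).
#' @export
apply_mutations <- function(scaffold_fp, ms) {
  sym <- scaffold_fp$symbols
  for (i in seq_len(nrow(ms$mutations))) {
    pos <- ms$mutations$position[i]
    slot <- as.character(pos)
    if (!slot %in% names(sym))
      stop("mutation at unannotated position ", pos)
    if (sym[[slot]] != ms$mutations$from[i])
      stop("from-symbol mismatch at position ", pos, ": scaffold has ",
           sym[[slot]], ", mutation expects ", ms$mutations$from[i])
    sym[[slot]] <- ms$mutations$to[i]
  }
  pocket_fingerprint(paste0(scaffold_fp$id, "_mut"), unname(sym),
                     scaffold_fp$positions)
}

#' Write mutation sets as TSV
#'
#' @param mss List of `mutation_set`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_sets <- function(mss, path) {
  rows <- lapply(mss, function(ms) {
    data.frame(scaffold = ms$scaffold, source = ms$source,
               mutations = if (nrow(ms$mutations))
                 paste(ms$mutations$label, collapse = ",") else "",
               n_mutations = nrow(ms$mutations),
               unresolvable = paste(ms$unresolvable, collapse = ","),
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
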