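#' Predict activity from key-residue conservation and domain integrity
#'
#' A member is predicted `likely_active` exactly when every catalytic
#' position carries the expected residue (e.g. the His33 catalytic base
#' and Tyr48) *and* no domain is disrupted; conservation of the catalytic
#' machinery is treated as the categorical indication of activity, and a
#' restructured domain vetoes it.
#'
#' @param fp The member's `pocket_fingerprint`.
#' @param disruption The member's `disruption_report`.
#' @param annotation A `ref_annotation`.
#' @param matrix Matrix for the pocket-similarity score.
#' @param gap_penalty Gap slot cost for the pocket-similarity score.
#' @return An `activity_prediction`: list with `id`, `catalytic_ok`
#'   (named logical per catalytic position), `disrupted`,
#'   `pocket_similarity` (fingerprint distance to the reference pocket)
#'   and `predicted_class`.
#' @export
predict_activity <- function(fp, disruption, annotation,
                             matrix = blosum62(), gap_penalty = 8) {
  if (!identical(fp$id, attr(disruption, "member_id")))
    stop("fingerprint and disruption report refer to different members")
  cat_pos <- annotation$catalytic$position
  expected <- toupper(annotation$catalytic$residue)
  ok <- fp$symbols[as.character(cat_pos)] == expected
  names(ok) <- cat_pos
  disrupted <- is_disrupted(disruption)
  cls <- if (all(ok) && !disrupted) "likely_active" else "likely_inactive"
  structure(list(id = fp$id, catalytic_ok = ok, disrupted = disrupted,
                 pocket_similarity = fingerprint_distance(
                   fp, reference_fingerprint(annotation), matrix,
                   gap_penalty),
                 predicted_class = cls),
            class = "activity_prediction")
}

#' @export
print.activity_prediction <- function(x, ...) {
  cat(x$id, ":", x$predicted_class,
      sprintf("(catalytic %d/%d, %sdisrupted, pocket distance %.2f)\n",
              sum(x$catalytic_ok), length(x$catalytic_ok),
              if (x$disrupted) "" else "not ", x$pocket_similarity))
  invisible(x)
}

#' Group pocket fingerprints into pocket types
#'
#' Single-linkage agglomeration under [fingerprint_distance()], stopping
#' when the minimum inter-cluster distance exceeds `threshold`
#' (`threshold = 0` degenerates to exact-identity grouping). Single
#' linkage mirrors grouping by connectivity, the way family branches are
#' grouped, rather than by compactness. Cluster ids are numbered by order
#' of first member; each cluster's representative fingerprint is the
#' member minimizing the summed distance to the cluster (ties to the
#' lexicographically smallest id).
#'
#' @param fps Non-empty list of `pocket_fingerprint`s.
#' @param matrix A `score_matrix`.
#' @param threshold Linkage distance threshold (>= 0).
#' @param gap_penalty Gap slot cost.
#' @return A list of `pocket_type_cluster`s: each a list with `cluster_id`,
#'   `members`, `representative` (member id) and `fingerprint`.
#' @export
cluster_pocket_types <- function(fps, matrix = blosum62(), threshold = 0,
                                 gap_penalty = 8) {
  stopifnot(length(fps) >= 1L, threshold >= 0)
  ids <- vapply(fps, `[[`, character(1L), "id")
  n <- length(fps)
  if (n == 1L) {
    memb <- list(1L)
  } else {
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n))
      D[i, j] <- D[j, i] <- fingerprint_distance(fps[[i]], fps[[j]], matrix,
                                                 gap_penalty)
    hc <- stats::hclust(stats::as.dist(D), method = "single")
    grp <- stats::cutree(hc, h = threshold)
    memb <- split(seq_len(n), grp)
  }
  # number clusters by order of first member
  memb <- memb[order(vapply(memb, min, integer(1L)))]
  lapply(seq_along(memb), function(k) {
    idx <- memb[[k]]
    if (length(idx) == 1L) rep_idx <- idx
    else {
      sums <- vapply(idx, function(i) sum(vapply(idx, function(j)
        fingerprint_distance(fps[[i]], fps[[j]], matrix, gap_penalty),
        numeric(1L))), numeric(1L))
      cand <- idx[sums == min(sums)]
      rep_idx <- cand[order(ids[cand], method = "radix")[1L]]
    }
    structure(list(cluster_id = k, members = ids[idx],
                   representative = ids[rep_idx],
                   fingerprint = fps[[rep_idx]]),
              class = "pocket_type_cluster")
  })
}

#' Read a substrate rule table from YAML
#'
#' @param path YAML rule table (see the bundled `substrate_rules.yaml`).
#' @return A list of `substrate_rule`s.
#' @export
read_substrate_rules <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y$substrates, function(s) {
    structure(list(id = as.character(s$id), name = s$name %||% "",
                   groups = lapply(s$groups, function(g) list(
                     threshold = g$threshold,
                     conditions = lapply(g$conditions, function(cc) list(
                       position = as.integer(cc$position),
                       allowed = norm_residue(unlist(cc$allowed)),
                       weight = cc$weight %||% 1)))),
                   disallowed = lapply(s$disallowed, function(dd) list(
                     position = as.integer(dd$position),
                     symbols = norm_residue(unlist(dd$symbols))))),
              class = "substrate_rule")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The bundled substrate rule table
#'
#' Ships the B-ring pocket hints at positions 79, 87/47 and 125 as an
#' editable starting point, not established truth: small residues (P/I)
#' or the E79+G125 combination open the pocket to para-methoxylated
#' B-rings, while D79 sterically excludes them.
#'
#' @return A list of `substrate_rule`s.
#' @export
default_substrate_rules <- function() {
  read_substrate_rules(system.file("extdata", "substrate_rules.yaml",
                                   package = "ssfe", mustWork = TRUE))
}

#' Score a fingerprint against substrate rules
#'
#' Per substrate: `incompatible` when any disallowed symbol is present;
#' otherwise `compatible` when any condition group reaches its weight
#' threshold (groups are alternatives); otherwise `unknown`. The reported
#' score is the best group's sum of satisfied condition weights.
#'
#' @param fp A `pocket_fingerprint`.
#' @param rules List of `substrate_rule`s; every rule position must be an
#'   annotated pocket position of the fingerprint.
#' @return Data frame with columns `substrate`, `verdict`, `score`.
#' @export
substrate_compatibility <- function(fp, rules = default_substrate_rules()) {
  at <- function(pos) {
    i <- match(pos, fp$positions)
    if (is.na(i))
      stop("rule references unannotated position ", pos)
    unname(fp$symbols[i])
  }
  rows <- lapply(rules, function(r) {
    bad <- any(vapply(r$disallowed, function(d)
      at(d$position) %in% d$symbols, logical(1L)))
    scores <- vapply(r$groups, function(g) {
      sum(vapply(g$conditions, function(cc)
        if (at(cc$position) %in% cc$allowed) cc$weight else 0,
        numeric(1L)))
    }, numeric(1L))
    thr_ok <- any(mapply(function(g, s) s >= g$threshold, r$groups, scores))
    verdict <- if (bad) "incompatible" else if (thr_ok) "compatible"
               else "unknown"
    data.frame(substrate = r$id, verdict = verdict,
               score = if (length(scores)) max(scores) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
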