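#' Assemble and validate a pipeline configuration
#'
#' Inputs may be given as file paths (FASTA / YAML) or as in-memory
#' objects (`seq_records`, `ref_annotation`, rule list); paths are checked
#' at validation time, parameters are checked against their documented
#' ranges.
#'
#' @param reference Reference enzyme: FASTA path or one-row `seq_records`.
#' @param homologs Candidate homologs: FASTA path or `seq_records`.
#' @param annotation Pocket annotation: YAML path or `ref_annotation`.
#' @param rules Substrate rules: YAML path, rule list, or `NULL` for the
#'   bundled table.
#' @param out_dir Output directory for artifacts, or `NULL` to skip
#'   writing.
#' @param gap_open,gap_extend Affine gap penalties.
#' @param distance_model `"poisson"` or `"p"`.
#' @param bootstrap_reps Bootstrap replicates (>= 1).
#' @param clade_cut Clade cut depth fraction in (0, 1].
#' @param max_insert,max_unaligned Disruption thresholds
#'   (see [detect_disruption()]).
#' @param cluster_threshold Pocket-type linkage threshold (>= 0).
#' @param k Representative panel size; `NULL` = number of pocket-type
#'   clusters among the eligible candidates.
#' @param gap_penalty Fingerprint gap slot cost.
#' @param scaffold Scaffold id for mutation proposals; default the
#'   reference.
#' @param seed Integer seed (bootstrap resampling).
#' @return An `ssfe_config` list.
#' @export
ssfe_config <- function(reference, homologs, annotation = NULL, rules = NULL,
                        out_dir = NULL, gap_open = 11, gap_extend = 1,
                        distance_model = "poisson", bootstrap_reps = 100L,
                        clade_cut = 0.5, max_insert = 10L,
                        max_unaligned = NULL, cluster_threshold = 0,
                        k = NULL, gap_penalty = 8, scaffold = NULL,
                        seed = 1L) {
  for (p in list(reference, homologs))
    if (is.character(p) && !file.exists(p)) stop("input not found: ", p)
  if (is.character(annotation) && !file.exists(annotation))
    stop("annotation not found: ", annotation)
  if (is.character(rules) && !file.exists(rules))
    stop("rule table not found: ", rules)
  stopifnot(gap_open >= 0, gap_extend >= 0, gap_extend <= gap_open,
            distance_model %in% c("poisson", "p"), bootstrap_reps >= 1,
            clade_cut > 0, clade_cut <= 1, max_insert >= 0,
            cluster_threshold >= 0, gap_penalty >= 0,
            is.null(k) || k >= 1)
  structure(list(reference = reference, homologs = homologs,
                 annotation = annotation, rules = rules, out_dir = out_dir,
                 gap_open = gap_open, gap_extend = gap_extend,
                 distance_model = distance_model,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 clade_cut = clade_cut, max_insert = as.integer(max_insert),
                 max_unaligned = max_unaligned,
                 cluster_threshold = cluster_threshold, k = k,
                 gap_penalty = gap_penalty, scaffold = scaffold,
                 seed = as.integer(seed)),
            class = "ssfe_config")
}

ssfe_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- withCallingHandlers(
    tryCatch(expr, error = function(e) {
      if (inherits(e, "ssfe_stage_error")) stop(e)
      stop(structure(
        list(message = paste0("stage ", name, ": ", conditionMessage(e)),
             call = NULL, stage = name),
        class = c("ssfe_stage_error", "error", "condition")))
    }))
  message(sprintf("[ssfe] stage %-12s %7.2fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

STAGE_ORDER <- c("input", "align", "tree", "fingerprint", "disrupt",
                 "classify", "cluster", "select", "design", "report")

#' Run the full SSFE pipeline
#'
#' Executes the four mining stages end to end: progressive alignment of
#' reference + homologs; neighbor-joining tree with bootstrap supports,
#' midpoint rooting and depth-fraction clade extraction; pocket
#' fingerprint and disruption screening per member; activity prediction,
#' pocket-type clustering and substrate-compatibility scoring; then
#' representative panel selection and pocket-transplant mutation
#' proposals for the scaffold. All stage timings are logged to standard
#' error; artifacts are written under `config$out_dir` when set. Identical
#' config + seed give byte-identical outputs.
#'
#' @param config An `ssfe_config`.
#' @return An `ssfe_report` (see Details) with the alignment, trees,
#'   clade partition, fingerprints, predictions, clusters, compatibility
#'   verdicts, representative panel, mutation sets and the per-member
#'   report table.
#' @export
run_ssfe <- function(config) {
  stopifnot(inherits(config, "ssfe_config"))
  inp <- ssfe_stage("input", {
    ref <- if (is.character(config$reference)) read_fasta(config$reference)
           else config$reference
    if (nrow(ref) != 1L) stop("reference FASTA must contain exactly 1 record")
    hom <- if (is.character(config$homologs)) read_fasta(config$homologs)
           else config$homologs
    if (nrow(hom) < 1L) stop("no homolog sequences supplied")
    ann <- if (is.null(config$annotation)) chi_era_annotation()
           else if (is.character(config$annotation))
             read_annotation(config$annotation, ref$residues[1L])
           else config$annotation
    if (!identical(ann$ref_id, ref$id[1L]))
      stop("annotation ref_id '", ann$ref_id,
           "' does not match the reference id '", ref$id[1L], "'")
    rules <- if (is.null(config$rules)) default_substrate_rules()
             else if (is.character(config$rules))
               read_substrate_rules(config$rules)
             else config$rules
    records <- seq_records(c(ref$id, hom$id),
                           c(ref$residues, hom$residues),
                           c(ref$description, hom$description))
    list(records = records, ann = ann, rules = rules)
  })
  records <- inp$records; ann <- inp$ann
  members <- setdiff(records$id, ann$ref_id)

  aln <- ssfe_stage("align",
    build_msa(records, blosum62(), config$gap_open, config$gap_extend))

  trees <- ssfe_stage("tree", {
    if (nrow(records) >= 3L) {
      unrooted <- bootstrap_support(aln, config$bootstrap_reps, config$seed,
                                    config$distance_model)
    } else {
      d <- distance_matrix(aln, config$distance_model)
      unrooted <- structure(
        list(edge = matrix(c(3L, 3L, 1L, 2L), ncol = 2L),
             edge.length = rep(d[1L, 2L] / 2, 2L),
             tip.label = rownames(d), Nnode = 1L),
        class = "phylo")
    }
    rooted <- midpoint_root(unrooted)
    partition <- cut_clades(rooted, config$clade_cut)
    list(unrooted = unrooted, rooted = rooted, partition = partition)
  })

  fps <- ssfe_stage("fingerprint", {
    out <- lapply(records$id, function(id)
      if (id == ann$ref_id) reference_fingerprint(ann)
      else extract_fingerprint(aln, ann, id))
    names(out) <- records$id
    out
  })

  disr <- ssfe_stage("disrupt", {
    out <- lapply(records$id, function(id)
      detect_disruption(aln, ann, id, config$max_insert,
                        config$max_unaligned))
    names(out) <- records$id
    out
  })

  preds <- ssfe_stage("classify", {
    out <- lapply(records$id, function(id)
      predict_activity(fps[[id]], disr[[id]], ann, blosum62(),
                       config$gap_penalty))
    names(out) <- records$id
    out
  })

  clusters <- ssfe_stage("cluster",
    cluster_pocket_types(unname(fps), blosum62(), config$cluster_threshold,
                         config$gap_penalty))

  compat <- ssfe_stage("classify", {
    out <- lapply(records$id, function(id)
      substrate_compatibility(fps[[id]], inp$rules))
    names(out) <- records$id
    out
  })

  sel <- ssfe_stage("select", {
    eligible <- vapply(records$id, function(id)
      id != ann$ref_id &&
        preds[[id]]$predicted_class == "likely_active" &&
        !any(fps[[id]]$symbols == GAP), logical(1L))
    cand_ids <- records$id[eligible]
    if (length(cand_ids) == 0L) {
      list(representatives = character(0L), k = 0L)
    } else {
      cand_fps <- fps[cand_ids]
      cand_clusters <- cluster_pocket_types(unname(cand_fps), blosum62(),
                                            config$cluster_threshold,
                                            config$gap_penalty)
      k <- config$k %||% length(cand_clusters)
      k <- min(k, length(cand_ids))
      list(representatives = select_representatives(
        unname(cand_fps), cand_clusters, reference_fingerprint(ann), k,
        trees$partition, blosum62(), config$gap_penalty), k = k)
    }
  })

  designs <- ssfe_stage("design", {
    scaffold_id <- config$scaffold %||% ann$ref_id
    if (!scaffold_id %in% names(fps))
      stop("scaffold '", scaffold_id, "' not among the aligned sequences")
    scaffold_fp <- fps[[scaffold_id]]
    lapply(sel$representatives, function(id)
      propose_mutations(scaffold_fp, fps[[id]]))
  })

  report <- ssfe_stage("report", {
    clade_of <- trees$partition$clade_id[
      match(records$id, trees$partition$member_id)]
    cluster_of <- stats::setNames(
      rep(vapply(clusters, `[[`, integer(1L), "cluster_id"),
          vapply(clusters, function(cl) length(cl$members), integer(1L))),
      unlist(lapply(clusters, `[[`, "members")))
    df <- data.frame(
      member_id = records$id,
      is_reference = records$id == ann$ref_id,
      clade_id = clade_of,
      fingerprint = vapply(fps[records$id], format, character(1L)),
      disrupted = vapply(disr[records$id], is_disrupted, logical(1L)),
      catalytic_ok = vapply(preds[records$id], function(p)
        all(p$catalytic_ok), logical(1L)),
      pocket_distance = sprintf("%.4f", vapply(
        preds[records$id], `[[`, numeric(1L), "pocket_similarity")),
      predicted_class = vapply(preds[records$id], `[[`, character(1L),
                               "predicted_class"),
      cluster_id = unname(cluster_of[records$id]),
      representative = records$id %in% sel$representatives,
      stringsAsFactors = FALSE)
    for (sub in vapply(inp$rules, `[[`, character(1L), "id"))
      df[[paste0("verdict_", sub)]] <- vapply(records$id, function(id) {
        cc <- compat[[id]]
        cc$verdict[cc$substrate == sub]
      }, character(1L))
    rownames(df) <- NULL
    df
  })

  res <- structure(list(config = config, records = records,
                        annotation = ann, msa = aln,
                        tree = trees$unrooted, rooted_tree = trees$rooted,
                        partition = trees$partition, fingerprints = fps,
                        disruption = disr, predictions = preds,
                        clusters = clusters, compatibility = compat,
                        representatives = sel$representatives,
                        mutation_sets = designs, report = report),
                   class = "ssfe_report")
  if (!is.null(config$out_dir)) write_ssfe_report(res, config$out_dir)
  res
}

#' Write all pipeline artifacts to a directory
#'
#' Emits `alignment.fasta`, `tree.nwk` (midpoint-rooted, canonical
#' Newick, bootstrap supports as node labels), `clades.tsv`,
#' `fingerprints.tsv`, `report.tsv` and `mutations.tsv`.
#'
#' @param x An `ssfe_report`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_ssfe_report <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(alignment = file.path(dir, "alignment.fasta"),
             tree = file.path(dir, "tree.nwk"),
             clades = file.path(dir, "clades.tsv"),
             fingerprints = file.path(dir, "fingerprints.tsv"),
             report = file.path(dir, "report.tsv"),
             mutations = file.path(dir, "mutations.tsv"))
  write_msa(x$msa, paths[["alignment"]])
  writeLines(write_newick(x$rooted_tree), paths[["tree"]])
  part <- x$partition
  part$depth <- sprintf("%.6f", part$depth)
  write.table(part, paths[["clades"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_fingerprints(unname(x$fingerprints), paths[["fingerprints"]])
  write.table(x$report, paths[["report"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_mutation_sets(x$mutation_sets, paths[["mutations"]])
  invisible(paths)
}

#' @export
print.ssfe_report <- function(x, ...) {
  cat("ssfe_report:", nrow(x$records), "sequences,",
      max(x$partition$clade_id), "clades,", length(x$clusters),
      "pocket types,", sum(x$report$predicted_class == "likely_active"),
      "likely active,", length(x$representatives), "representatives\n")
  invisible(x)
}
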