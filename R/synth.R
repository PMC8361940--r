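#' Specify a synthetic homolog family
#'
#' Describes a clade-structured family descended from a reference: each
#' clade carries its own pocket variant (symbol assignment at annotated
#' positions), background substitutions hit non-pocket sites at a fixed
#' per-site rate, and an out-group receives a long contiguous insertion
#' inside the second domain span, mimicking domain restructuring by
#' flexible loops.
#'
#' @param n_clades Number of in-family clades.
#' @param members_per_clade Members generated per clade.
#' @param background_rate Per-site substitution probability in `[0, 1)`
#'   outside the pocket.
#' @param pocket_variants Optional list (length `n_clades`) of named
#'   character vectors `position -> symbol`; `NULL` uses
#'   [default_pocket_variants()].
#' @param outgroup_n Number of out-group members.
#' @param insertion_len Length of the out-group insertion (residues).
#' @param seed Integer seed; the whole family is deterministic given it.
#' @param noise_at_pocket Also apply background substitutions at
#'   (non-catalytic) pocket positions. Off by default so that
#'   clustering-recovery tests are separated from robustness tests.
#' @return A `family_spec`.
#' @export
family_spec <- function(n_clades = 4L, members_per_clade = 15L,
                        background_rate = 0.02, pocket_variants = NULL,
                        outgroup_n = 5L, insertion_len = 15L, seed = 1L,
                        noise_at_pocket = FALSE) {
  stopifnot(n_clades >= 1L, members_per_clade >= 1L,
            background_rate >= 0, background_rate < 1,
            outgroup_n >= 0L, insertion_len >= 0L)
  structure(list(n_clades = as.integer(n_clades),
                 members_per_clade = as.integer(members_per_clade),
                 background_rate = background_rate,
                 pocket_variants = pocket_variants,
                 outgroup_n = as.integer(outgroup_n),
                 insertion_len = as.integer(insertion_len),
                 seed = as.integer(seed),
                 noise_at_pocket = isTRUE(noise_at_pocket)),
            class = "family_spec")
}

#' Default planted pocket variants
#'
#' Clade 1 keeps the reference pocket; later clades receive fixed
#' substitutions at non-catalytic pocket positions echoing naturally
#' observed pocket types (small residue at 79, the E79+G125 combination,
#' the R87+E47 hydrogen-bonding pair, and further B-ring swaps for deeper
#' clades). Catalytic positions are never touched.
#'
#' @param annotation A `ref_annotation`.
#' @param n_clades Number of clades.
#' @return List of named character vectors (`position -> symbol`).
#' @export
default_pocket_variants <- function(annotation, n_clades) {
  templates <- list(
    character(0L),
    c("79" = "P"),
    c("79" = "E", "125" = "G"),
    c("87" = "R", "47" = "E"),
    c("40" = "N", "122" = "S"),
    c("73" = "F", "91" = "A"),
    c("37" = "T", "75" = "Y"),
    c("12" = "L", "135" = "Y"))
  if (n_clades > length(templates))
    stop("no default variants for more than ", length(templates), " clades")
  variants <- templates[seq_len(n_clades)]
  ref <- strsplit(annotation$ref_seq, "")[[1L]]
  for (v in variants) {
    pos <- as.integer(names(v))
    stopifnot(all(pos %in% annotation$pocket$position),
              all(ref[pos] != v))
  }
  variants
}

#' Simulate a synthetic homolog family with ground truth
#'
#' Emits the reference unchanged, then per clade member: the clade's
#' pocket variant written at the annotated positions, plus background
#' substitutions (uniform over the 19 alternative residues) at non-pocket
#' sites. Out-group members carry the reference pocket but receive a
#' contiguous insertion of random residues at a random site inside the
#' second domain span. Identical seeds give byte-identical output.
#'
#' @param spec A `family_spec`.
#' @param annotation A `ref_annotation` (default: the bundled reference
#'   profile).
#' @return A list with `records` (a `seq_records`: reference first) and
#'   `truth` (data frame `member_id`, `clade_id`, `pocket_type`,
#'   `disrupted`; the reference and out-group carry pocket type 1).
#' @export
simulate_family <- function(spec, annotation = chi_era_annotation()) {
  stopifnot(inherits(spec, "family_spec"))
  variants <- spec$pocket_variants %||%
    default_pocket_variants(annotation, spec$n_clades)
  if (length(variants) != spec$n_clades)
    stop("need one pocket variant per clade")
  for (v in variants) {
    if (length(v) == 0L) next
    if (!all(v %in% AA_LETTERS))
      stop("pocket variant symbol '", setdiff(v, AA_LETTERS)[1L],
           "' is not an amino-acid letter")
    if (!all(as.integer(names(v)) %in% annotation$pocket$position))
      stop("pocket variant position outside the annotation")
  }
  ref <- strsplit(annotation$ref_seq, "")[[1L]]
  pocket_pos <- annotation$pocket$position
  cat_pos <- annotation$catalytic$position
  mutable <- setdiff(seq_along(ref),
                     if (spec$noise_at_pocket) cat_pos else pocket_pos)
  span2 <- annotation$domains[min(2L, nrow(annotation$domains)), ]

  ids <- character(0L); seqs <- character(0L)
  clade_id <- integer(0L); ptype <- integer(0L); disrupted <- logical(0L)

  with_seed(spec$seed, {
    for (cl in seq_len(spec$n_clades)) {
      v <- variants[[cl]]
      for (mbr in seq_len(spec$members_per_clade)) {
        s <- ref
        if (length(v)) s[as.integer(names(v))] <- v
        s[mutable] <- mutate_sites(s[mutable], spec$background_rate)
        ids <- c(ids, sprintf("clade%d_m%02d", cl, mbr))
        seqs <- c(seqs, paste(s, collapse = ""))
        clade_id <- c(clade_id, cl); ptype <- c(ptype, cl)
        disrupted <- c(disrupted, FALSE)
      }
    }
    for (og in seq_len(spec$outgroup_n)) {
      s <- ref
      s[mutable] <- mutate_sites(s[mutable], spec$background_rate)
      if (spec$insertion_len > 0L) {
        # insert strictly between two reference positions inside the span,
        # avoiding annotated pocket positions as anchors is not required:
        # the insertion sits between columns, never replacing residues
        at <- sample(seq.int(span2$start, span2$end - 1L), 1L)
        ins <- sample(AA_LETTERS, spec$insertion_len, replace = TRUE)
        s <- c(s[seq_len(at)], ins, s[seq.int(at + 1L, length(s))])
      }
      ids <- c(ids, sprintf("outgroup_m%02d", og))
      seqs <- c(seqs, paste(s, collapse = ""))
      clade_id <- c(clade_id, NA_integer_); ptype <- c(ptype, 1L)
      disrupted <- c(disrupted, spec$insertion_len > 0L)
    }
  })

  records <- seq_records(c(annotation$ref_id, ids),
                         c(annotation$ref_seq, seqs))
  truth <- data.frame(
    member_id = c(annotation$ref_id, ids),
    clade_id = c(NA_integer_, clade_id),
    pocket_type = c(1L, ptype),
    disrupted = c(FALSE, disrupted),
    stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

# substitute each site with probability `rate`, uniformly over the 19
# alternative residues
mutate_sites <- function(chars, rate) {
  if (rate <= 0 || length(chars) == 0L) return(chars)
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    alt <- setdiff(AA_LETTERS, chars[i])
    chars[i] <- alt[sample.int(length(alt), 1L)]
  }
  chars
}

#' Build a deterministic toy structure
#'
#' Residues (one CA atom each) are laid out on a line 5 Angstrom apart;
#' one ligand atom is placed at each requested distance from residue 1.
#' Used to exercise the structure-derived pocket definition.
#'
#' @param n_residues Number of polymer residues (>= 1).
#' @param ligand_offsets Non-negative distances (Angstrom) from residue 1;
#'   empty for a ligand-free structure.
#' @param ligand_name Residue name given to the ligand atoms.
#' @return A `structure_model`.
#' @export
make_toy_structure <- function(n_residues, ligand_offsets = numeric(0L),
                               ligand_name = "LIG") {
  stopifnot(n_residues >= 1L)
  if (any(ligand_offsets < 0)) stop("ligand offsets must be non-negative")
  residues <- data.frame(
    chain = "A", resno = seq_len(n_residues), resname = "ALA", atom = "CA",
    element = "C", x = 5 * (seq_len(n_residues) - 1L), y = 0, z = 0,
    stringsAsFactors = FALSE)
  ligands <- if (length(ligand_offsets))
    data.frame(chain = "L", resno = 1L, resname = ligand_name,
               atom = paste0("C", seq_along(ligand_offsets)), element = "C",
               x = -ligand_offsets, y = 0, z = 0, stringsAsFactors = FALSE)
  else residues[0L, ]
  structure(list(residues = residues, ligands = ligands),
            class = "structure_model")
}

#' Write a simulated family to disk
#'
#' Emits the FASTA, the TSV truth table and the annotation config used.
#'
#' @param fam Output of [simulate_family()].
#' @param annotation The `ref_annotation` used.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_family <- function(fam, annotation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "family.fasta"),
             truth = file.path(dir, "truth.tsv"),
             annotation = file.path(dir, "annotation.yaml"))
  write_fasta(fam$records, paths[["fasta"]])
  write.table(fam$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_annotation(annotation, paths[["annotation"]])
  invisible(paths)
}
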