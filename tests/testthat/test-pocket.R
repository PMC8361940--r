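test_that("the bundled reference profile is internally consistent", {
  ann <- chi_era_annotation()
  expect_equal(nrow(ann$pocket), 21L)
  expect_equal(ann$catalytic$position, c(33L, 48L))
  expect_equal(ann$catalytic$residue, c("H", "Y"))
  expect_true(all(ann$catalytic$position %in% ann$pocket$position))
  expect_true(ann$pocket$provisional[ann$pocket$position == 47L])
  ref <- strsplit(ann$ref_seq, "")[[1L]]
  expect_equal(ref[ann$pocket$position], ann$pocket$residue)
})

test_that("annotation validation rejects residue mismatches", {
  ann <- chi_era_annotation()
  bad <- ann$pocket
  bad$residue[1L] <- "W"
  expect_error(
    ref_annotation(ann$ref_id, ann$ref_seq, ann$catalytic, bad, ann$domains),
    "does not match")
})

test_that("position maps follow the alignment column walk", {
  mm <- msa(c("ref", "mem"), c("ARNDCQEG", "ARNDCQEG"))
  expect_equal(as.integer(build_position_map(mm, "ref", "mem")), 1:8)

  # two-residue deletion spanning reference positions 5-6
  mm <- msa(c("ref", "mem"), c("ARNDCQEG", "ARND--EG"))
  map <- build_position_map(mm, "ref", "mem")
  expect_equal(as.integer(map), c(1:4, NA, NA, 5L, 6L))

  # three-residue insertion after reference position 4
  mm <- msa(c("ref", "mem"), c("ARND---CQEG", "ARNDKKKCQEG"))
  map <- build_position_map(mm, "ref", "mem")
  expect_equal(as.integer(map), c(1:4, 8:11))
  mapped <- as.integer(map)[!is.na(map)]
  expect_false(is.unsorted(mapped, strictly = TRUE))

  expect_error(build_position_map(mm, "ref", "nope"), "nope")
})

test_that("the reference fingerprint equals the annotated residues", {
  ann <- chi_era_annotation()
  mm <- ref_based_msa(other = ann$ref_seq)
  fp <- extract_fingerprint(mm, ann, ann$ref_id)
  expect_equal(unname(fp$symbols), ann$pocket$residue)
  # the key catalytic/binding sub-fingerprint in reference numbering
  expect_equal(paste(fp$symbols[as.character(c(33, 48, 69, 71, 101))],
                     collapse = ""), "HYETQ")
})

test_that("member fingerprints reflect substitutions and deletions", {
  ann <- chi_era_annotation()
  ref <- ann$ref_seq
  mem <- ref
  substr(mem, 79, 79) <- "A"
  mm <- ref_based_msa(mem = mem)
  fp <- extract_fingerprint(mm, ann, "mem")
  rfp <- reference_fingerprint(ann)
  diff <- which(fp$symbols != rfp$symbols)
  expect_equal(fp$positions[diff], 79L)
  expect_equal(unname(fp$symbols[diff]), "A")

  mem2 <- ref
  substr(mem2, 125, 125) <- "-"          # deletion aligned at column 125
  mm <- msa(c(ann$ref_id, "mem2"), c(ref, mem2))
  fp2 <- extract_fingerprint(mm, ann, "mem2")
  expect_equal(unname(fp2$symbols[fp2$positions == 125L]), "-")
})

test_that("fingerprint distance is a symmetric premetric with gap costs", {
  ann <- chi_era_annotation()
  f <- reference_fingerprint(ann)
  expect_equal(fingerprint_distance(f, f), 0)

  pos <- 1:3
  fD <- pocket_fingerprint("d", c("D", "A", "A"), pos)
  fE <- pocket_fingerprint("e", c("E", "A", "A"), pos)
  # (s(D,D) + s(E,E))/2 - s(D,E) = (6 + 5)/2 - 2
  expect_equal(fingerprint_distance(fD, fE), 3.5)
  expect_equal(fingerprint_distance(fE, fD), 3.5)

  fX <- pocket_fingerprint("x", c("X", "A", "A"), pos)
  fG <- pocket_fingerprint("g", c("-", "A", "A"), pos)
  expect_equal(fingerprint_distance(fX, fG, gap_penalty = 8), 8)
  expect_equal(fingerprint_distance(fG, fG), 0)   # both-gap slots are free

  expect_error(
    fingerprint_distance(fD, pocket_fingerprint("s", c("A", "A"), 1:2)),
    "different pocket annotations")

  set.seed(21)
  for (i in 1:10) {
    a <- rand_fp("a", ann$pocket$position)
    b <- rand_fp("b", ann$pocket$position)
    expect_gte(fingerprint_distance(a, b), 0)
    expect_equal(fingerprint_distance(a, b), fingerprint_distance(b, a))
  }
})

test_that("domain disruption is detected from insertions and deletions", {
  ann <- chi_era_annotation()
  ref <- ann$ref_seq
  mm <- ref_based_msa(mem = ref)
  rep0 <- detect_disruption(mm, ann, "mem")
  expect_false(is_disrupted(rep0))
  expect_equal(rep0$max_insert_run, c(0L, 0L))
  expect_equal(rep0$unaligned, c(0L, 0L))

  # 15-residue insertion inside the solvent-exposed span
  at <- 170L
  ins <- strrep("K", 15L)
  mem <- paste0(substr(ref, 1, at), ins, substr(ref, at + 1, nchar(ref)))
  refrow <- paste0(substr(ref, 1, at), strrep("-", 15L),
                   substr(ref, at + 1, nchar(ref)))
  mm <- msa(c(ann$ref_id, "mem"), c(refrow, mem))
  rep1 <- detect_disruption(mm, ann, "mem", max_insert = 10L)
  expect_true(is_disrupted(rep1))
  expect_equal(rep1$max_insert_run[rep1$domain == "solvent_exposed"], 15L)
  # a looser threshold tolerates the same insertion
  expect_false(is_disrupted(detect_disruption(mm, ann, "mem",
                                              max_insert = 20L)))

  # an entire span deleted
  mem2 <- paste0(substr(ref, 1, 140), strrep("-", 70L))
  mm2 <- msa(c(ann$ref_id, "m2"), c(ref, mem2))
  rep2 <- detect_disruption(mm2, ann, "m2", max_insert = 10L)
  expect_true(is_disrupted(rep2))
  expect_equal(rep2$unaligned[rep2$domain == "solvent_exposed"], 70L)
})

test_that("structure-derived pockets use an inclusive heavy-atom cutoff", {
  s <- make_toy_structure(3L, c(3.0))
  expect_equal(pocket_from_structure(s, "LIG", 4.5), 1L)

  far <- make_toy_structure(3L, c(100))
  expect_equal(pocket_from_structure(far, "LIG", 4.5), integer(0L))

  boundary <- make_toy_structure(3L, c(4.5))
  expect_equal(pocket_from_structure(boundary, "LIG", 4.5), 1L)

  expect_error(pocket_from_structure(s, "NAD", 4.5), "NAD")
  two <- s
  two$ligands <- rbind(two$ligands,
                       transform(two$ligands, chain = "M", resno = 2L))
  expect_error(pocket_from_structure(two, "LIG", 4.5), "multiple")

  none <- make_toy_structure(3L)
  expect_error(pocket_from_structure(none, "LIG", 4.5), "no ligand")
})

test_that("fingerprint TSV round trips", {
  ann <- chi_era_annotation()
  set.seed(4)
  fps <- list(reference_fingerprint(ann),
              rand_fp("m1", ann$pocket$position),
              rand_fp("m2", ann$pocket$position, gap_at = 125L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fingerprints(fps, f)
  back <- read_fingerprints(f)
  expect_equal(lapply(back, format), lapply(fps, format))
  expect_equal(back[[2L]]$positions, ann$pocket$position)
})
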