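test_that("global_align handles the basic affine-gap contracts", {
  idm <- identity_matrix()
  r <- global_align("HIS", "HIS", idm, 1, 1)
  expect_equal(r$score, 3)
  expect_equal(r$a_aln, "HIS")
  expect_equal(r$b_aln, "HIS")

  b62 <- blosum62()
  r <- global_align("ARND", "AND", b62, 11, 1)
  expect_equal(r$score, 5)                      # 4 + 6 + 6 - 11
  expect_equal(r$a_aln, "ARND")
  expect_equal(r$b_aln, "A-ND")

  expect_error(global_align("AC", "", b62), "non-empty")
  r <- global_align("AC", "A", b62, 11, 1)
  expect_equal(r$score, b62["A", "A"] - 11)

  expect_error(global_align("AB", "AA", b62), "B")  # B not in alphabet
})

test_that("global_align matches the exhaustive-enumeration oracle", {
  b62 <- blosum62()
  set.seed(101)
  for (i in 1:25) {
    a <- rand_pep(sample(1:7, 1L))
    b <- rand_pep(sample(1:7, 1L))
    go <- sample(3:11, 1L); ge <- sample(1:3, 1L)
    expect_equal(global_align(a, b, b62, go, ge)$score,
                 oracle_align_score(a, b, b62, go, ge),
                 info = paste(a, b, go, ge))
  }
})

test_that("global_align agrees with Biostrings pairwiseAlignment", {
  b62m <- unclass(blosum62())[1:20, 1:20]
  set.seed(77)
  for (i in 1:15) {
    a <- rand_pep(sample(3:12, 1L), c("A", "C", "D", "E", "K", "W"))
    b <- rand_pep(sample(3:12, 1L), c("A", "C", "D", "E", "K", "W"))
    # Biostrings charges open+extend for the first gap column
    ref <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = b62m, gapOpening = 10, gapExtension = 1,
      type = "global", scoreOnly = TRUE)
    expect_equal(global_align(a, b, blosum62(), 11, 1)$score, ref)
  }
})

test_that("alignment score is symmetric and self-score is the diagonal sum", {
  b62 <- blosum62()
  set.seed(11)
  for (i in 1:10) {
    a <- rand_pep(sample(2:9, 1L), c("A", "R", "N", "D", "K"))
    b <- rand_pep(sample(2:9, 1L), c("A", "R", "N", "D", "K"))
    expect_equal(global_align(a, b, b62)$score, global_align(b, a, b62)$score)
    expect_equal(global_align(a, a, b62)$score,
                 sum(diag(b62)[strsplit(a, "")[[1L]]]))
  }
})

test_that("build_msa aligns identical sequences without gaps", {
  rec <- seq_records(c("a", "b", "c"), rep("MKVLIGHT", 3L))
  x <- build_msa(rec)
  expect_equal(x$ncol, 8L)
  expect_equal(unname(x$aln), rep("MKVLIGHT", 3L))
})

test_that("build_msa degaps to its inputs and stays within the column bound", {
  rec <- seq_records(c("s1", "s2", "s3"), c("PELICAN", "PELCAN", "ELICAN"))
  x <- build_msa(rec)
  for (k in 1:3)
    expect_equal(gsub("-", "", x$aln[[rec$id[k]]]), rec$residues[k])
  expect_lte(x$ncol, 8L)
  # frozen regression of the deterministic tie rules
  expect_equal(unname(x$aln), c("PELICAN", "PEL-CAN", "-ELICAN"))
})

test_that("build_msa of two sequences equals global_align", {
  rec <- seq_records(c("x", "y"), c("MKVLIG", "MKLIG"))
  x <- build_msa(rec)
  pw <- global_align("MKVLIG", "MKLIG")
  expect_equal(unname(x$aln), c(pw$a_aln, pw$b_aln))
  expect_error(build_msa(rec[1L, ]), "at least 2")
})

test_that("build_msa degap property holds on random inputs", {
  set.seed(303)
  for (rep in 1:5) {
    n <- sample(3:6, 1L)
    rec <- seq_records(sprintf("r%d", 1:n),
                       vapply(seq_len(n), function(i)
                         rand_pep(sample(8:20, 1L),
                                  c("A", "R", "N", "D", "C", "Q", "E", "G")),
                         character(1L)))
    x <- build_msa(rec)
    for (k in seq_len(n))
      expect_equal(gsub("-", "", x$aln[[rec$id[k]]]), rec$residues[k])
    cols <- as.matrix(x)
    expect_false(any(colSums(cols != "-") == 0L))  # no all-gap column
  }
})

test_that("distance_matrix implements p and poisson models", {
  mm <- msa(c("r1", "r2"), c("AAAAAAAAAA", "AAAAAAAAAA"))
  expect_equal(distance_matrix(mm, "p")["r1", "r2"], 0)

  mm <- msa(c("r1", "r2"), c("AAAAAAAAAA", "AAAAACCCCC"))
  expect_equal(distance_matrix(mm, "poisson")["r1", "r2"], -log(0.5),
               tolerance = 1e-12)

  mm <- msa(c("r1", "r2"), c("AAAA----", "----CCCC"))
  expect_error(distance_matrix(mm, "p"), "no compared columns")

  mm <- msa(c("r1", "r2"), c("AAAA", "CCCC"))
  expect_error(distance_matrix(mm, "poisson"), "saturated")
})

test_that("poisson correction dominates the p distance", {
  set.seed(9)
  for (rep in 1:10) {
    rows <- vapply(1:3, function(i) rand_pep(30, c("A", "C", "G", "T", "K")),
                   character(1L))
    mm <- msa(c("a", "b", "c"), rows)
    dp <- distance_matrix(mm, "p")
    dq <- distance_matrix(mm, "poisson")
    expect_true(all(dq >= dp - 1e-12))
    expect_equal(dq == 0, dp == 0)
  }
})
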