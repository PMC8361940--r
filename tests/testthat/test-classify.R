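make_report <- function(id, disrupted = FALSE) {
  structure(data.frame(domain = "catalytic", max_insert_run = 0L,
                       unaligned = 0L, span_disrupted = disrupted,
                       stringsAsFactors = FALSE),
            member_id = id, disrupted = disrupted,
            class = c("disruption_report", "data.frame"))
}

test_that("activity prediction follows catalytic conservation and integrity", {
  ann <- chi_era_annotation()
  fp <- reference_fingerprint(ann)
  fp$id <- "m"

  # intact His33 + Tyr48, intact domains -> likely active
  p <- predict_activity(fp, make_report("m"), ann)
  expect_equal(p$predicted_class, "likely_active")
  expect_true(all(p$catalytic_ok))
  expect_equal(p$pocket_similarity, 0)

  # catalytic base replaced -> inactive no matter what
  fpq <- fp
  fpq$symbols[["33"]] <- "Q"
  p <- predict_activity(fpq, make_report("m"), ann)
  expect_equal(p$predicted_class, "likely_inactive")
  expect_false(p$catalytic_ok[["33"]])

  # intact catalytic residues but restructured domains -> inactive
  p <- predict_activity(fp, make_report("m", disrupted = TRUE), ann)
  expect_equal(p$predicted_class, "likely_inactive")

  expect_error(predict_activity(fp, make_report("other"), ann),
               "different members")
})

test_that("breaking residues or adding disruption never activates", {
  ann <- chi_era_annotation()
  set.seed(33)
  for (i in 1:10) {
    fp <- rand_fp("m", ann$pocket$position)
    for (dis in c(FALSE, TRUE)) {
      p0 <- predict_activity(fp, make_report("m", dis), ann)
      # break one catalytic residue
      fpb <- fp
      slot <- as.character(sample(ann$catalytic$position, 1L))
      fpb$symbols[[slot]] <- if (fpb$symbols[[slot]] == "G") "P" else "G"
      p1 <- predict_activity(fpb, make_report("m", dis), ann)
      expect_false(p0$predicted_class == "likely_inactive" &&
                     p1$predicted_class == "likely_active")
      # add disruption
      p2 <- predict_activity(fp, make_report("m", TRUE), ann)
      expect_false(p0$predicted_class == "likely_inactive" &&
                     p2$predicted_class == "likely_active")
    }
  }
})

test_that("pocket-type clustering groups by single linkage", {
  pos <- 1:3
  fA1 <- pocket_fingerprint("a1", c("A", "A", "A"), pos)
  fA2 <- pocket_fingerprint("a2", c("A", "A", "A"), pos)
  fB1 <- pocket_fingerprint("b1", c("C", "C", "C"), pos)
  fB2 <- pocket_fingerprint("b2", c("C", "C", "C"), pos)

  cl <- cluster_pocket_types(list(fA1, fB1, fA2, fB2), threshold = 0)
  expect_length(cl, 2L)
  expect_setequal(cl[[1L]]$members, c("a1", "a2"))
  expect_setequal(cl[[2L]]$members, c("b1", "b2"))

  cl1 <- cluster_pocket_types(list(fA1, fA2), threshold = 0)
  expect_length(cl1, 1L)
  cl1b <- cluster_pocket_types(list(fA1, fA2), threshold = 100)
  expect_length(cl1b, 1L)

  # chained pair + far member under an identity-like matrix:
  # d(f1,f2) = d(f2,f3) = 2, d(f1,f3) = 4, far member at >= 10
  idm <- identity_matrix(2L, 0L)
  f1 <- pocket_fingerprint("f1", c("A", "A", "A", "A", "A", "A", "A"), 1:7)
  f2 <- pocket_fingerprint("f2", c("C", "A", "A", "A", "A", "A", "A"), 1:7)
  f3 <- pocket_fingerprint("f3", c("C", "D", "A", "A", "A", "A", "A"), 1:7)
  f4 <- pocket_fingerprint("f4", c("E", "E", "E", "E", "E", "E", "E"), 1:7)
  cl <- cluster_pocket_types(list(f1, f2, f3, f4), idm, threshold = 3)
  expect_length(cl, 2L)
  expect_setequal(cl[[1L]]$members, c("f1", "f2", "f3"))  # chained
  expect_equal(cl[[2L]]$members, "f4")

  # threshold 0 groups identical fingerprints only
  set.seed(8)
  fps <- c(replicate(3, rand_fp("x", 1:7), simplify = FALSE),
           list(f1, f2))
  for (i in seq_along(fps)) fps[[i]]$id <- sprintf("m%d", i)
  cl0 <- cluster_pocket_types(fps, threshold = 0)
  keys <- vapply(fps, format, character(1L))
  expect_length(cl0, length(unique(keys)))
  for (cc in cl0) {
    idx <- match(cc$members, vapply(fps, `[[`, character(1L), "id"))
    expect_length(unique(keys[idx]), 1L)
  }
})

test_that("cluster representatives minimize the summed within-cluster distance", {
  idm <- identity_matrix(2L, 0L)
  # b is the 1-mutation hub between a and c
  fa <- pocket_fingerprint("a", c("A", "A", "A"), 1:3)
  fb <- pocket_fingerprint("b", c("A", "A", "C"), 1:3)
  fc <- pocket_fingerprint("c", c("A", "C", "C"), 1:3)
  cl <- cluster_pocket_types(list(fa, fb, fc), idm, threshold = 5)
  expect_length(cl, 1L)
  expect_equal(cl[[1L]]$representative, "b")
})

test_that("substrate rules encode the B-ring pocket hints", {
  ann <- chi_era_annotation()
  rules <- default_substrate_rules()
  ref <- reference_fingerprint(ann)

  # the reference pocket: D79 + R125 + K87 fits the para-hydroxy substrate
  v <- substrate_compatibility(ref, rules)
  expect_equal(v$verdict[v$substrate == "1a"], "compatible")
  # but D79 sterically excludes the para-methoxy substrate
  expect_equal(v$verdict[v$substrate == "4a"], "incompatible")

  with79 <- function(sym, extra = NULL) {
    fp <- ref
    fp$symbols[["79"]] <- sym
    for (nm in names(extra)) fp$symbols[[nm]] <- extra[[nm]]
    fp
  }
  v <- substrate_compatibility(with79("P"), rules)
  expect_equal(v$verdict[v$substrate == "4a"], "compatible")
  v <- substrate_compatibility(with79("I"), rules)
  expect_equal(v$verdict[v$substrate == "4a"], "compatible")
  # the alternative E79 + G125 route
  v <- substrate_compatibility(with79("E", c("125" = "G")), rules)
  expect_equal(v$verdict[v$substrate == "4a"], "compatible")
  # E79 alone is not enough evidence
  v <- substrate_compatibility(with79("E"), rules)
  expect_equal(v$verdict[v$substrate == "4a"], "unknown")

  bad_rule <- rules[1:1]
  bad_rule[[1L]]$groups[[1L]]$conditions[[1L]]$position <- 999L
  expect_error(substrate_compatibility(ref, bad_rule), "999")
})
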