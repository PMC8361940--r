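test_that("nj_tree solves the 3-taxon closed form", {
  lab <- c("A", "B", "C")
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3L, dimnames = list(lab, lab))
  t <- nj_tree(dist_matrix(d))
  expect_identical(write_newick(t), "(A:1.000000,B:2.000000,C:4.000000);")
})

test_that("nj_tree recovers an additive 4-taxon matrix exactly", {
  # path lengths of ((A:1,B:2):1,(C:3,D:4))
  lab <- c("A", "B", "C", "D")
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4L, dimnames = list(lab, lab))
  t <- nj_tree(dist_matrix(d))
  expect_true("C|D" %in% tree_splits(t) || "A|B" %in% tree_splits(t))
  expect_equal(ape::cophenetic.phylo(t)[lab, lab], d, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("Q-matrix ties are broken by the smallest label pair", {
  lab <- c("A", "B", "C", "D")
  d <- matrix(2, 4L, 4L, dimnames = list(lab, lab)); diag(d) <- 0
  t <- nj_tree(dist_matrix(d))
  # A and B joined first; all leaf-to-leaf paths remain 2
  expect_match(write_newick(t), "(A:1.000000,B:1.000000)", fixed = TRUE)
  expect_true(all(abs(ape::cophenetic.phylo(t)[lab, lab] - d) < 1e-12))
})

test_that("nj_tree recovers random additive trees (topology and lengths)", {
  set.seed(202)
  for (rep in 1:25) {
    t0 <- rand_blen_tree(sample(5:8, 1L))
    d <- ape::cophenetic.phylo(t0)
    d <- d[sort(rownames(d)), sort(rownames(d))]
    t1 <- nj_tree(dist_matrix(d))
    expect_identical(tree_splits(t1), tree_splits(t0))
    expect_lt(max(abs(ape::cophenetic.phylo(t1)[rownames(d), rownames(d)] - d)),
              1e-9)
  }
})

test_that("midpoint_root splits the longest path in half", {
  t <- read_newick("(A:1,B:3);")
  r <- midpoint_root(t)
  depth <- ape::node.depth.edgelength(r)
  expect_equal(depth[match(c("A", "B"), r$tip.label)], c(2, 2))

  # chain with internal node: A -1- x -3- B, plus a short C stub
  t <- read_newick("((A:1,C:0.1):1,B:2);")
  r <- midpoint_root(t)
  depth <- ape::node.depth.edgelength(r)
  expect_equal(depth[match("A", r$tip.label)], 2)
  expect_equal(depth[match("B", r$tip.label)], 2)
  expect_true(ape::is.rooted(r))
})

test_that("midpoint_root tie and degenerate contracts hold", {
  # symmetric tree: all leaf pairs across the middle edge tie; the chosen
  # path involves the smallest label A
  t <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  r <- midpoint_root(t)
  depth <- ape::node.depth.edgelength(r)
  expect_equal(depth[match("A", r$tip.label)], 2)

  # all-zero branch lengths: root lands next to the smallest leaf
  t <- read_newick("((B:0,C:0):0,(A:0,D:0):0);")
  r <- midpoint_root(t)
  expect_true(ape::is.rooted(r))
  expect_equal(sort(r$tip.label), c("A", "B", "C", "D"))

  # idempotence on an already-midpoint tree
  t <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  r1 <- midpoint_root(t)
  r2 <- midpoint_root(r1)
  d1 <- sort(ape::node.depth.edgelength(r1)[1:4])
  d2 <- sort(ape::node.depth.edgelength(r2)[1:4])
  expect_equal(d1, d2)
})

test_that("cut_clades partitions leaves at a depth fraction", {
  nw <- "((a1:0.05,(a2:0.05,a3:0.05):0.02):0.95,(b1:0.05,(b2:0.05,b3:0.05):0.02):0.95);"
  t <- read_newick(nw)
  p <- cut_clades(t, 0.5)
  expect_equal(max(p$clade_id), 2L)
  expect_setequal(p$member_id[p$clade_id == 1L], c("a1", "a2", "a3"))
  expect_setequal(p$member_id[p$clade_id == 2L], c("b1", "b2", "b3"))

  # fraction 1: cut at the maximum depth, every leaf its own clade
  p1 <- cut_clades(t, 1)
  expect_equal(max(p1$clade_id), 6L)

  # fraction near 0 on a binary root: the two root subtrees
  p0 <- cut_clades(t, 1e-9)
  expect_equal(max(p0$clade_id), 2L)

  # always a partition
  for (p in list(p, p1, p0)) {
    expect_setequal(p$member_id, t$tip.label)
    expect_false(anyDuplicated(p$member_id) > 0L)
  }
})

test_that("bootstrap_support behaves on unanimous signal and is seeded", {
  mm <- msa(c("A", "B", "C", "D"),
            c("AAAA", "AAAA", "CCCC", "CCCA"))
  bt <- bootstrap_support(mm, 100L, seed = 42L, model = "p")
  supp <- suppressWarnings(as.numeric(bt$node.label))
  supp <- supp[!is.na(supp)]
  expect_equal(supp, 100)

  one <- bootstrap_support(mm, 1L, seed = 3L, model = "p")
  s1 <- suppressWarnings(as.numeric(one$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))

  bt2 <- bootstrap_support(mm, 100L, seed = 42L, model = "p")
  expect_identical(write_newick(midpoint_root(bt)),
                   write_newick(midpoint_root(bt2)))

  # supports always within [0, 100]
  set.seed(1)
  rows <- vapply(1:5, function(i) rand_pep(40, c("A", "C", "D", "E")),
                 character(1L))
  bt3 <- bootstrap_support(msa(sprintf("s%d", 1:5), rows), 20L, seed = 9L,
                           model = "p")
  s3 <- suppressWarnings(as.numeric(bt3$node.label))
  expect_true(all(s3[!is.na(s3)] >= 0 & s3[!is.na(s3)] <= 100))
})
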