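#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (Saitou-Nei with the usual Q-matrix
#' formulation). Ties in the Q minimum are broken by the lexicographically
#' smallest label pair, where an agglomerated node carries the smallest
#' leaf label among its descendants. Negative branch lengths are clamped
#' to zero with the deficit moved to the sibling branch, so the tree is
#' usable for depth-based clade cutting downstream.
#'
#' @param d A `dist_matrix` with at least 3 labels.
#' @return An unrooted [ape::phylo] tree (basal trifurcation) whose tip
#'   labels are exactly the matrix labels.
#' @export
nj_tree <- function(d) {
  stopifnot(inherits(d, "dist_matrix"))
  labels <- rownames(d)
  n <- length(labels)
  if (n < 3L) stop("neighbor joining needs at least 3 labels")

  recs <- lapply(labels, function(l)
    list(children = NULL, lens = NULL, label = l, minlab = l))
  active <- seq_len(n)
  D <- unclass(d)

  new_rec <- function(ch, lens) {
    recs[[length(recs) + 1L]] <<- list(
      children = ch, lens = lens, label = NA_character_,
      minlab = min(vapply(ch, function(i) recs[[i]]$minlab, character(1L))))
    length(recs)
  }

  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    ml <- vapply(active, function(i) recs[[i]]$minlab, character(1L))
    k1 <- pmin(ml[cand[, 1L]], ml[cand[, 2L]])
    k2 <- pmax(ml[cand[, 1L]], ml[cand[, 2L]])
    pick <- order(k1, k2, method = "radix")[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]

    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    u <- new_rec(c(active[i], active[j]), c(li, lj))

    others <- setdiff(seq_len(m), c(i, j))
    du <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D <- rbind(cbind(D[others, others, drop = FALSE], du),
               c(du, 0))
    active <- c(active[others], u)
  }

  # final trifurcation, closed form
  dab <- D[1L, 2L]; dac <- D[1L, 3L]; dbc <- D[2L, 3L]
  lens <- pmax(0, c((dab + dac - dbc) / 2,
                    (dab + dbc - dac) / 2,
                    (dac + dbc - dab) / 2))
  root <- new_rec(active, lens)
  recs_to_phylo(recs, root, labels)
}

# convert recursive node records to an ape phylo (cladewise order)
recs_to_phylo <- function(recs, root, labels) {
  ntip <- length(labels)
  env <- new.env(parent = emptyenv())
  env$next_int <- ntip + 1L
  env$edges <- matrix(0L, nrow = 0L, ncol = 2L)
  env$lens <- numeric(0L)
  assign_id <- function(rid) {
    rec <- recs[[rid]]
    if (is.null(rec$children)) return(match(rec$label, labels))
    my <- env$next_int
    env$next_int <- my + 1L
    for (k in seq_along(rec$children)) {
      cid <- assign_id(rec$children[k])
      env$edges <- rbind(env$edges, c(my, cid))
      env$lens <- c(env$lens, rec$lens[k])
    }
    my
  }
  assign_id(root)
  tr <- structure(list(edge = env$edges, edge.length = env$lens,
                       tip.label = labels, Nnode = env$next_int - ntip - 1L),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

# undirected adjacency view of a phylo: list(neigh[[node]], len[[node]],
# labels (tips), node_label (internal, by node id))
phylo_adjacency <- function(t) {
  nn <- length(t$tip.label) + t$Nnode
  neigh <- vector("list", nn)
  len <- vector("list", nn)
  for (i in seq_len(nrow(t$edge))) {
    a <- t$edge[i, 1L]; b <- t$edge[i, 2L]
    l <- if (is.null(t$edge.length)) NA_real_ else t$edge.length[i]
    neigh[[a]] <- c(neigh[[a]], b); len[[a]] <- c(len[[a]], l)
    neigh[[b]] <- c(neigh[[b]], a); len[[b]] <- c(len[[b]], l)
  }
  nlab <- rep("", nn)
  if (!is.null(t$node.label))
    nlab[length(t$tip.label) + seq_len(t$Nnode)] <- t$node.label
  list(neigh = neigh, len = len, ntip = length(t$tip.label),
       tip.label = t$tip.label, node_label = nlab)
}

# root an adjacency on edge (a, b), at distance `la` from a; returns a
# rooted phylo with the original tip labels and carried node labels
root_adjacency_at <- function(adj, a, b, la) {
  nn <- length(adj$neigh)
  root <- nn + 1L
  # sever a-b, connect both to root
  drop_edge <- function(node, other) {
    k <- which(adj$neigh[[node]] == other)[1L]
    adj$neigh[[node]] <<- adj$neigh[[node]][-k]
    adj$len[[node]] <<- adj$len[[node]][-k]
  }
  lab_full <- adj$len[[a]][which(adj$neigh[[a]] == b)[1L]]
  drop_edge(a, b); drop_edge(b, a)
  adj$neigh[[root]] <- c(a, b)
  adj$len[[root]] <- c(la, lab_full - la)
  adj$node_label <- c(adj$node_label, "")

  ntip <- adj$ntip
  env <- new.env(parent = emptyenv())
  env$next_int <- ntip + 1L
  env$edges <- matrix(0L, nrow = 0L, ncol = 2L)
  env$lens <- numeric(0L)
  env$nlab <- character(0L)
  build <- function(node, parent) {
    if (node <= ntip) return(node)
    my <- env$next_int
    env$next_int <- my + 1L
    env$nlab[my - ntip] <- adj$node_label[node]
    nb <- adj$neigh[[node]]; ln <- adj$len[[node]]
    for (k in seq_along(nb)) {
      if (nb[k] == parent) next
      cid <- build(nb[k], node)
      env$edges <- rbind(env$edges, c(my, cid))
      env$lens <- c(env$lens, ln[k])
    }
    my
  }
  build(root, 0L)
  tr <- structure(list(edge = env$edges, edge.length = env$lens,
                       tip.label = adj$tip.label,
                       Nnode = env$next_int - ntip - 1L,
                       node.label = env$nlab),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path. Ties
#' on the path length are broken by the lexicographically smallest leaf
#' pair; if every branch length is zero the root is placed on the edge
#' adjacent to the lexicographically smallest leaf.
#'
#' @param t An [ape::phylo] tree with at least 2 leaves (a rooted input is
#'   unrooted first).
#' @return A rooted [ape::phylo], strictly binary below the root.
#' @export
midpoint_root <- function(t) {
  stopifnot(inherits(t, "phylo"))
  ntip <- length(t$tip.label)
  if (ntip < 2L) stop("midpoint rooting needs at least 2 leaves")
  if (ntip == 2L) {
    tot <- sum(t$edge.length)
    tr <- structure(list(edge = matrix(c(3L, 3L, 1L, 2L), ncol = 2L),
                         edge.length = c(tot / 2, tot / 2),
                         tip.label = t$tip.label, Nnode = 1L),
                    class = "phylo")
    return(ape::reorder.phylo(tr, "cladewise"))
  }
  if (ape::is.rooted(t)) t <- ape::unroot(t)

  D <- ape::dist.nodes(t)
  tipD <- D[seq_len(ntip), seq_len(ntip), drop = FALSE]
  dmax <- max(tipD)
  adj <- phylo_adjacency(t)
  if (dmax <= 0) {
    u <- which(t$tip.label == min(t$tip.label))[1L]
    p <- adj$neigh[[u]][1L]
    return(root_adjacency_at(adj, u, p, 0))
  }
  cand <- which(tipD == dmax, arr.ind = TRUE)
  cand <- cand[cand[, 1L] != cand[, 2L], , drop = FALSE]
  l1 <- pmin(t$tip.label[cand[, 1L]], t$tip.label[cand[, 2L]])
  l2 <- pmax(t$tip.label[cand[, 1L]], t$tip.label[cand[, 2L]])
  pick <- order(l1, l2, method = "radix")[1L]
  uv <- c(cand[pick, 1L], cand[pick, 2L])
  u <- uv[order(t$tip.label[uv], method = "radix")[1L]]
  v <- setdiff(uv, u)[1L]
  # walk the u -> v path until the midpoint edge
  path <- ape::nodepath(t, u, v)
  half <- dmax / 2
  cum <- 0
  for (k in seq_len(length(path) - 1L)) {
    step <- D[path[k], path[k + 1L]]
    if (cum + step >= half) {
      return(root_adjacency_at(adj, path[k], path[k + 1L], half - cum))
    }
    cum <- cum + step
  }
  stop("internal error: midpoint not found on path")  # nocov
}

#' Cut a rooted tree into clades at a depth threshold
#'
#' Cuts every edge crossing depth `height_fraction * max leaf depth`
#' (measured as branch-length distance from the root). The leaf set of
#' each subtree hanging below a cut is one clade; leaves too shallow to
#' reach the cut depth become singleton clades. Clades are numbered by
#' their lexicographically smallest member.
#'
#' @param t A rooted [ape::phylo] with branch lengths.
#' @param height_fraction Cut depth as a fraction of the maximum leaf
#'   depth, in (0, 1].
#' @return A `clade_partition`: data frame with columns `clade_id`,
#'   `member_id`, `depth` (depth of the clade's subtending node).
#' @export
cut_clades <- function(t, height_fraction = 0.5) {
  stopifnot(inherits(t, "phylo"), height_fraction > 0, height_fraction <= 1)
  if (!ape::is.rooted(t)) stop("cut_clades needs a rooted tree")
  t <- ape::reorder.phylo(t, "cladewise")
  ntip <- length(t$tip.label)
  depth <- ape::node.depth.edgelength(t)
  h <- height_fraction * max(depth[seq_len(ntip)])
  parent <- integer(ntip + t$Nnode)
  parent[t$edge[, 2L]] <- t$edge[, 1L]
  parent[ntip + 1L] <- ntip + 1L  # root points at itself (depth 0)

  roots <- which(seq_along(depth) != ntip + 1L &
                   depth >= h & depth[parent] < h)
  tips_under <- function(v) {
    if (v <= ntip) return(t$tip.label[v])
    out <- character(0L)
    stack <- v
    kids <- split(t$edge[, 2L], t$edge[, 1L])
    while (length(stack)) {
      x <- stack[[1L]]; stack <- stack[-1L]
      if (x <= ntip) out <- c(out, t$tip.label[x])
      else stack <- c(stack, kids[[as.character(x)]])
    }
    out
  }
  clades <- lapply(roots, tips_under)
  depths <- depth[roots]
  covered <- unlist(clades)
  orphan <- setdiff(t$tip.label, covered)
  if (length(orphan)) {
    oid <- match(orphan, t$tip.label)
    clades <- c(clades, as.list(orphan))
    depths <- c(depths, depth[oid])
  }
  ord <- order(vapply(clades, min, character(1L)), method = "radix")
  clades <- clades[ord]; depths <- depths[ord]
  df <- data.frame(
    clade_id = rep.int(seq_along(clades), lengths(clades)),
    member_id = unlist(clades),
    depth = rep.int(depths, lengths(clades)),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("clade_partition", "data.frame"))
}

# canonical key of the bipartition induced by a tip-label set: the side
# not containing the overall smallest label
bipart_key <- function(side, all_labels) {
  other <- setdiff(all_labels, side)
  s <- if (min(all_labels) %in% side) other else side
  paste(sort(s), collapse = "|")
}

# bipartition keys for every internal (non-basal) node of a tree
tree_bipart_keys <- function(t) {
  ntip <- length(t$tip.label)
  t <- ape::reorder.phylo(t, "cladewise")
  sets <- vector("list", ntip + t$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- t$tip.label[i]
  for (i in rev(seq_len(nrow(t$edge)))) {
    p <- t$edge[i, 1L]; ch <- t$edge[i, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  internal <- setdiff(seq.int(ntip + 1L, ntip + t$Nnode), ntip + 1L)
  keys <- vapply(internal, function(v) {
    n <- length(sets[[v]])
    if (n < 2L || n > ntip - 2L) return(NA_character_)
    bipart_key(sets[[v]], t$tip.label)
  }, character(1L))
  list(nodes = internal, keys = keys)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Builds the reference tree (`nj_tree` on `distance_matrix(msa, model)`),
#' then resamples alignment columns with replacement `n_reps` times,
#' rebuilds a tree per replicate, and annotates each internal edge of the
#' reference tree with the percentage of replicates containing the same
#' leaf bipartition. Deterministic for a given `seed`.
#'
#' @param msa An `msa` object.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for the column resampling.
#' @param model Distance model passed to [distance_matrix()].
#' @return The unrooted reference tree with supports (0-100) in
#'   `node.label`.
#' @export
bootstrap_support <- function(msa, n_reps = 100L, seed = 1L,
                              model = "poisson") {
  stopifnot(n_reps >= 1L)
  ref <- nj_tree(distance_matrix(msa, model))
  bk <- tree_bipart_keys(ref)
  counts <- stats::setNames(numeric(length(bk$keys)), bk$keys)

  cols <- as.matrix(msa)
  with_seed(seed, {
    for (rep in seq_len(n_reps)) {
      idx <- sample.int(ncol(cols), replace = TRUE)
      rm_ <- cols[, idx, drop = FALSE]
      rmsa <- msa(msa$ids, apply(rm_, 1L, paste, collapse = ""))
      rt <- nj_tree(distance_matrix(rmsa, model))
      rkeys <- tree_bipart_keys(rt)$keys
      hit <- names(counts) %in% rkeys
      counts[hit] <- counts[hit] + 1
    }
  })
  supp <- 100 * counts / n_reps
  ntip <- length(ref$tip.label)
  nlab <- rep("", ref$Nnode)
  ok <- !is.na(bk$keys)
  nlab[bk$nodes[ok] - ntip] <- sprintf("%g", unname(supp[ok]))
  ref$node.label <- nlab
  ref
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}
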