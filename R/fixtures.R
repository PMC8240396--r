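# Seeded synthetic-data generators: random binary trees, overlapping
# source-tree pairs derived from a common model tree, and the small
# constructed instances used throughout the tests.
#
# All generators draw through withr::with_seed, so regeneration with the
# same arguments is bit-identical.

# insert leaf `lab` onto edge (a, b); reuses the adjacency-surgery helpers
insert_leaf_on_edge <- function(t, a, b, lab) {
  t <- tree_remove_edge(t, a, b)
  t <- tree_add_node(t)           # subdivision node
  z <- n_nodes(t)
  t <- tree_add_node(t, lab)      # new leaf
  l <- n_nodes(t)
  t <- tree_add_edge(t, a, z)
  t <- tree_add_edge(t, z, b)
  t <- tree_add_edge(t, z, l)
  t
}

#' Random unrooted binary tree
#'
#' Uniform over topologies: leaves are inserted in sorted order, each onto
#' an edge chosen uniformly at random; every topology arises from exactly
#' one insertion sequence.
#'
#' @param labels character vector of at least 3 distinct labels
#' @param seed integer seed
#' @return a binary `rfs_tree`
#' @export
random_binary_tree <- function(labels, seed = 1L) {
  labels <- sort(unique(as.character(labels)))
  n <- length(labels)
  if (n < 3L) stop("need at least 3 labels")
  withr::with_seed(as.integer(seed), {
    em <- cbind(rep(n + 1L, 3L), 1:3)
    if (n > 3L) {
      for (l in 4:n) {
        z <- n + l - 2L
        k <- sample.int(nrow(em), 1L)
        em <- rbind(em[-k, , drop = FALSE],
                    c(em[k, 1L], z), c(z, em[k, 2L]), c(z, l))
      }
    }
    edge_matrix_to_tree(em, labels)
  })
}

# one random subtree-prune-regraft move on a binary tree; assumes the RNG
# is already seeded by the caller; returns the tree unchanged if no legal
# move exists
random_spr <- function(t) {
  em <- tree_edges(t)
  # candidate directed prune edges (u, v): u internal, and the remaining
  # component (u's side) retains at least two leaves
  cand <- list()
  for (k in seq_len(nrow(em))) {
    for (dir in 1:2) {
      u <- em[k, dir]; v <- em[k, 3L - dir]
      if (!is.na(t$label[u])) next
      kept <- reachable_labels(t, from = u, avoid = v)
      if (length(kept) >= 2L) cand[[length(cand) + 1L]] <- c(u, v)
    }
  }
  if (!length(cand)) return(t)
  pick <- cand[[sample.int(length(cand), 1L)]]
  u <- pick[1L]; v <- pick[2L]
  w <- setdiff(t$adj[[u]], v)     # u is internal in a binary tree: |w| = 2
  t <- tree_remove_edge(t, u, v)
  t <- tree_remove_edge(t, u, w[1L])
  t <- tree_remove_edge(t, u, w[2L])
  t <- tree_add_edge(t, w[1L], w[2L])
  # regraft edges: edges of the remaining component, avoiding the merged
  # edge (w1, w2) when an alternative exists, so the move tends to change
  # the topology
  emr <- tree_edges(t)
  keep_nodes <- c(u, v, reachable_nodes(t, v))
  inrem <- !(emr[, 1L] %in% keep_nodes) & !(emr[, 2L] %in% keep_nodes)
  merged <- (emr[, 1L] == min(w) & emr[, 2L] == max(w))
  pool <- which(inrem & !merged)
  if (!length(pool)) pool <- which(inrem)
  k <- pool[sample.int(length(pool), 1L)]
  a <- emr[k, 1L]; b <- emr[k, 2L]
  # reuse u as the subdivision node
  t <- tree_remove_edge(t, a, b)
  t <- tree_add_edge(t, a, u)
  t <- tree_add_edge(t, u, b)
  t <- tree_add_edge(t, u, v)
  t
}

reachable_nodes <- function(t, from, avoid = integer(0)) {
  seen <- rep(FALSE, n_nodes(t))
  seen[avoid] <- TRUE
  seen[from] <- TRUE
  stack <- from
  out <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    for (nb in t$adj[[v]]) {
      if (!seen[nb]) {
        seen[nb] <- TRUE
        stack <- c(stack, nb)
      }
    }
  }
  setdiff(out, from)
}

#' Pair of overlapping source trees derived from a model tree
#'
#' Emulates the two-source-tree setting: the first tree is the model tree
#' restricted to the overlap plus its own private leaves; the second starts
#' from the model's backbone on the overlap, optionally perturbed by random
#' subtree-prune-regraft moves (restricted to the backbone, so the
#' disagreement affects the supertree optimum), and then receives its own
#' private leaves at random positions. With zero moves the pair is
#' compatible and the optimal total Robinson-Foulds score is 0.
#'
#' @param model a binary `rfs_tree`
#' @param overlap character vector of at least 4 shared leaf labels,
#'   a subset of the model's leaves
#' @param extra_per_side number of private leaves for each tree (capped at
#'   half the non-overlap leaves)
#' @param disagreement_spr number of SPR moves applied to the second
#'   tree's backbone
#' @param seed integer seed
#' @return list of two binary `rfs_tree`s whose shared leaf set is exactly
#'   `overlap`
#' @export
overlapping_pair <- function(model, overlap, extra_per_side = 2L,
                             disagreement_spr = 0L, seed = 1L) {
  overlap <- sort(unique(as.character(overlap)))
  stopifnot(length(overlap) >= 4L)
  if (length(setdiff(overlap, tree_labels(model)))) {
    stop("overlap must be a subset of the model tree's leaves")
  }
  rest <- setdiff(tree_labels(model), overlap)
  k <- min(as.integer(extra_per_side), length(rest) %/% 2L)
  withr::with_seed(as.integer(seed), {
    rest <- sample(rest)
    e1 <- if (k > 0L) rest[seq_len(k)] else character(0)
    e2 <- if (k > 0L) rest[k + seq_len(k)] else character(0)
    t1 <- restrict_tree(model, c(overlap, e1))
    b2 <- restrict_tree(model, overlap)
    if (disagreement_spr > 0L) {
      for (i in seq_len(disagreement_spr)) b2 <- random_spr(b2)
    }
    t2 <- b2
    for (lab in e2) {
      em <- tree_edges(t2)
      k2 <- sample.int(nrow(em), 1L)
      t2 <- insert_leaf_on_edge(t2, em[k2, 1L], em[k2, 2L], lab)
    }
    list(t1 = canonical_tree(t1), t2 = canonical_tree(t2))
  })
}

#' Profile of single-split trees with star and caterpillar companions
#'
#' On leaf set 1..n, builds the n-3 source trees whose only internal edge
#' separates leaves 1..i+1 from i+2..n, together with the star tree and the
#' caterpillar tree on the same leaves. The star minimizes the total RF
#' distance over all (not necessarily binary) trees while the caterpillar
#' maximizes the total split support, which is why the relaxed versions of
#' the two optimization problems are not equivalent.
#'
#' @param n integer, at least 5
#' @return list with `profile` (list of n-3 trees), `star`, `caterpillar`,
#'   and `labels`
#' @export
single_edge_profile <- function(n) {
  n <- as.integer(n)
  if (n < 5L) stop("construction requires n >= 5")
  labs <- as.character(seq_len(n))
  one <- function(i) {
    adj <- vector("list", n + 2L)
    va <- n + 1L; vb <- n + 2L
    for (l in seq_len(i + 1L)) { adj[[l]] <- va; adj[[va]] <- c(adj[[va]], l) }
    for (l in (i + 2L):n) { adj[[l]] <- vb; adj[[vb]] <- c(adj[[vb]], l) }
    adj[[va]] <- c(adj[[va]], vb)
    adj[[vb]] <- c(adj[[vb]], va)
    new_rfs_tree(adj, c(labs, NA, NA))
  }
  star_adj <- c(lapply(seq_len(n), function(l) n + 1L), list(seq_len(n)))
  star <- new_rfs_tree(star_adj, c(labs, NA))
  # caterpillar: internal path v_2..v_(n-1); leaf 1 and 2 on v_2, leaf n on
  # v_(n-1), leaf i on v_i
  nint <- n - 2L
  adj <- vector("list", n + nint)
  vid <- function(i) n + i - 1L            # v_i for i in 2..n-1
  link <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
  }
  link(1L, vid(2L))
  for (i in 2:(n - 1L)) link(i, vid(i))
  link(n, vid(n - 1L))
  for (i in 2:(n - 2L)) link(vid(i), vid(i + 1L))
  caterpillar <- new_rfs_tree(adj, c(labs, rep(NA_character_, nint)))
  list(profile = lapply(seq_len(n - 3L), one), star = star,
       caterpillar = caterpillar, labels = labs)
}

#' Small worked supertree instance with known optimum
#'
#' An 8-label pair of binary source trees sharing five leaves, for which the
#' optimal supertree has total Robinson-Foulds distance exactly 2 to the
#' sources, together with one optimal supertree. Useful as a golden test:
#' no supertree does better, and exhaustive search confirms it.
#'
#' @return list with `t1`, `t2` (source trees) and `supertree` (an optimal
#'   supertree on the union of their leaves)
#' @export
toy_instance <- function() {
  list(t1 = parse_newick("(A,((B,x),((C,y),(D,E))));"),
       t2 = parse_newick("(A,(C,(z,(B,(D,E)))));"),
       supertree = parse_newick("(A,((C,y),(z,((B,x),(D,E)))));"))
}
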