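# Single-level divide-and-conquer merge: split a taxon set via a guide-tree
# edge into two overlapping subsets, estimate a tree on each subset, and
# combine the two subset trees with the exact two-tree supertree algorithm.
# When the subset trees are correct restrictions of a model tree and every
# short quartet of the model tree lies within one subset, the model tree is
# the unique compatibility supertree and the merge recovers it exactly.

#' Indices of the internal edges of a tree
#'
#' @param t an `rfs_tree`
#' @return integer vector of row indices into [tree_edges()]
#' @export
internal_edges <- function(t) {
  em <- tree_edges(t)
  which(is.na(t$label[em[, 1L]]) & is.na(t$label[em[, 2L]]))
}

# tie-inclusive p nearest leaves within the subtree entered from `start`,
# with distances counted from `anchor` (an endpoint of the decomposition
# edge); returns labels
nearest_in_subtree <- function(t, anchor, start, p) {
  n <- n_nodes(t)
  dist <- rep(NA_integer_, n)
  dist[anchor] <- 0L
  dist[start] <- 1L
  queue <- start
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (u in t$adj[[v]]) {
      if (is.na(dist[u])) {
        dist[u] <- dist[v] + 1L
        queue <- c(queue, u)
      }
    }
  }
  lv <- which(!is.na(t$label) & !is.na(dist))
  lv <- lv[lv != anchor]
  d <- dist[lv]
  if (length(lv) <= p) return(t$label[lv])
  thr <- sort(d)[p]
  t$label[lv[d <= thr]]
}

#' Edge-based decomposition of a guide tree
#'
#' Deleting an internal edge and its endpoints leaves four subtrees; `P`
#' collects, from each subtree, the `p` topologically nearest leaves to the
#' edge (including all ties). The two overlapping taxon subsets are
#' `A` and `B` extended by `P`, where `[A|B]` is the edge's bipartition.
#'
#' @param guide a binary `rfs_tree`
#' @param edge an index into [tree_edges()] (see [internal_edges()]) or a
#'   length-2 vector of adjacent node ids
#' @param p positive integer: nearest-leaf count per subtree
#' @return list with `edge` (node pair), `p`, `shared` (the set P),
#'   `set_a`, `set_b` (label vectors with `set_a` containing the canonical
#'   first side)
#' @export
decompose_by_edge <- function(guide, edge, p = 1L) {
  stopifnot(inherits(guide, "rfs_tree"), p >= 1L)
  if (!is_binary_tree(guide)) stop("guide tree must be binary")
  if (length(edge) == 1L) {
    em <- tree_edges(guide)
    stopifnot(edge >= 1L, edge <= nrow(em))
    u <- em[edge, 1L]; v <- em[edge, 2L]
  } else {
    u <- edge[1L]; v <- edge[2L]
    if (!(v %in% guide$adj[[u]])) stop("not an edge of the guide tree")
  }
  if (!is.na(guide$label[u]) || !is.na(guide$label[v])) {
    stop("decomposition edge must be internal (leaf edges have no four subtrees)")
  }
  side_v <- reachable_labels(guide, from = v, avoid = u)
  side_u <- setdiff(tree_labels(guide), side_v)
  shared <- character(0)
  for (w in setdiff(guide$adj[[u]], v)) {
    shared <- c(shared, nearest_in_subtree(guide, u, w, p))
  }
  for (w in setdiff(guide$adj[[v]], u)) {
    shared <- c(shared, nearest_in_subtree(guide, v, w, p))
  }
  shared <- sort(unique(shared))
  s <- make_split(side_u, side_v)
  list(edge = c(u, v), p = as.integer(p), shared = shared,
       set_a = sort(union(s$side_a, shared)),
       set_b = sort(union(s$side_b, shared)))
}

#' Short quartets of a binary tree
#'
#' For every internal edge, a short quartet takes one closest leaf
#' (tie-inclusive) from each of the four subtrees around the edge; the tree
#' induces the quartet topology pairing the two leaves from the same side.
#' The set of induced short quartet trees determines the tree.
#'
#' @param t a binary `rfs_tree` with at least one internal edge
#' @return list of records, each with `labels` (4 sorted labels) and
#'   `topology` (an `rfs_split` pairing them as in `t`), de-duplicated
#' @export
short_quartets <- function(t) {
  stopifnot(is_binary_tree(t))
  ie <- internal_edges(t)
  if (!length(ie)) stop("tree has no internal edge")
  em <- tree_edges(t)
  out <- list()
  for (k in ie) {
    u <- em[k, 1L]; v <- em[k, 2L]
    nu <- setdiff(t$adj[[u]], v)
    nv <- setdiff(t$adj[[v]], u)
    cu <- lapply(nu, function(w) nearest_in_subtree(t, u, w, 1L))
    cv <- lapply(nv, function(w) nearest_in_subtree(t, v, w, 1L))
    for (a1 in cu[[1L]]) for (a2 in cu[[2L]]) {
      for (b1 in cv[[1L]]) for (b2 in cv[[2L]]) {
        s <- make_split(c(a1, a2), c(b1, b2))
        out[[s$key]] <- list(labels = s$universe, topology = s)
      }
    }
  }
  unname(out[unique(names(out))])
}

#' Does a pair of overlapping subsets cover all short quartets?
#'
#' The sufficient condition for exact recovery: every short quartet of the
#' model tree must lie entirely within one of the two taxon subsets.
#'
#' @param model a binary `rfs_tree`
#' @param set_a,set_b character label vectors
#' @return logical
#' @export
short_quartets_covered <- function(model, set_a, set_b) {
  all(vapply(short_quartets(model), function(q) {
    all(q$labels %in% set_a) || all(q$labels %in% set_b)
  }, TRUE))
}

most_balanced_internal_edge <- function(guide) {
  ie <- internal_edges(guide)
  if (!length(ie)) stop("guide tree has no internal edge")
  em <- tree_edges(guide)
  imbalance <- vapply(ie, function(k) {
    side <- reachable_labels(guide, from = em[k, 2L], avoid = em[k, 1L])
    abs(length(tree_labels(guide)) - 2L * length(side))
  }, 0L)
  ie[which.min(imbalance)]
}

#' Divide-and-conquer merge through a guide-tree decomposition
#'
#' Decomposes the taxon set by a guide-tree edge (default: a most balanced
#' internal edge), obtains a tree on each overlapping subset from the
#' supplied estimator, and merges the two subset trees with the exact
#' two-tree supertree algorithm.
#'
#' @param guide a binary `rfs_tree` on the full taxon set
#' @param estimator function taking a character label vector and returning
#'   a binary `rfs_tree` on exactly those labels
#' @param p nearest-leaf count for the shared set
#' @param edge optional decomposition edge (see [decompose_by_edge()])
#' @param seed seed passed to the merge's resolution step
#' @return the merged `rfs_tree` on the full taxon set
#' @export
dactal_merge <- function(guide, estimator, p = 1L, edge = NULL, seed = 1L) {
  if (is.null(edge)) edge <- most_balanced_internal_edge(guide)
  dec <- decompose_by_edge(guide, edge, p)
  ta <- estimator(dec$set_a)
  tb <- estimator(dec$set_b)
  if (!setequal(tree_labels(ta), dec$set_a)) {
    stop("estimator returned a tree on the wrong leaf set (subset A)")
  }
  if (!setequal(tree_labels(tb), dec$set_b)) {
    stop("estimator returned a tree on the wrong leaf set (subset B)")
  }
  exact_rfs_2(ta, tb, seed = seed)$tree
}
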