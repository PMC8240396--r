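# The exact two-tree Robinson-Foulds / Split-Fit supertree algorithm.
#
# Phases: (1) backbone decomposition (decompose.R); (2) an initial star
# supertree whose centre is adjacent to every shared leaf and to every extra
# subtree root -- this already maximizes the p2 part of the split support;
# (3) place the extra subtrees behind each trivial bipartition onto the
# matching pendant path, then repeatedly refine with the non-trivial
# bipartitions selected by the maximum-weight independent set of the
# incompatibility graph, each refinement raising p1 by exactly w*; (4)
# arbitrary (seeded) resolution to a binary tree.

# --- small adjacency-surgery helpers (operate on a tree, return a tree) ---

tree_add_node <- function(tree, label = NA_character_) {
  tree$adj[[length(tree$adj) + 1L]] <- integer(0)
  tree$label <- c(tree$label, label)
  tree
}

tree_add_edge <- function(tree, u, v) {
  tree$adj[[u]] <- c(tree$adj[[u]], v)
  tree$adj[[v]] <- c(tree$adj[[v]], u)
  tree
}

tree_remove_edge <- function(tree, u, v) {
  tree$adj[[u]] <- setdiff(tree$adj[[u]], v)
  tree$adj[[v]] <- setdiff(tree$adj[[v]], u)
  tree
}

# --- refinement state ----------------------------------------------------

# Builds the initial supertree and the H / sv bookkeeping.
# State fields:
#   tree        growing supertree on S (never renumbered during refinement)
#   ctx         shared context
#   center      node id of the initial hub
#   extra_node  integer vector: extra gid -> node id of its root in `tree`
#   extra_nodes list: extra gid -> all node ids of that extra in `tree`
#   node_extra  named integer: root node id (as character) -> extra gid
#   h           list: node id (as character) -> pending split keys
#   sv          named integer: pending split key -> node to split
rfs_init_state <- function(ctx) {
  nx <- length(ctx$x)
  label <- c(NA_character_, ctx$x)
  adj <- c(list(seq_len(nx) + 1L), as.list(seq_len(nx) * 0L + 1L))
  center <- 1L
  extra_node <- integer(length(ctx$extras))
  extra_nodes <- vector("list", length(ctx$extras))
  for (gid in seq_along(ctx$extras)) {
    e <- ctx$extras[[gid]]
    src <- if (e$source == 1L) ctx$t1 else ctx$t2
    map <- integer(n_nodes(src))
    base <- length(adj)
    map[e$nodes_src] <- base + seq_along(e$nodes_src)
    for (v in e$nodes_src) adj[[map[v]]] <- integer(0)
    label <- c(label, src$label[e$nodes_src])
    for (v in e$nodes_src) {
      for (u in src$adj[[v]]) {
        if (u %in% e$nodes_src && v < u) {
          adj[[map[v]]] <- c(adj[[map[v]]], map[u])
          adj[[map[u]]] <- c(adj[[map[u]]], map[v])
        }
      }
    }
    r <- map[e$root_src]
    adj[[center]] <- c(adj[[center]], r)
    adj[[r]] <- c(adj[[r]], center)
    extra_node[gid] <- r
    extra_nodes[[gid]] <- map[e$nodes_src]
  }
  tree <- new_rfs_tree(adj, label, validate = FALSE)
  structure(list(tree = tree, ctx = ctx, center = center,
                 extra_node = extra_node, extra_nodes = extra_nodes,
                 node_extra = stats::setNames(seq_along(extra_node),
                                              as.character(extra_node)),
                 h = stats::setNames(list(ctx$nontriv), as.character(center)),
                 sv = stats::setNames(rep(center, length(ctx$nontriv)),
                                      ctx$nontriv)),
            class = "rfs_state")
}

#' Initial supertree of the two source trees
#'
#' A star whose centre is adjacent to every shared leaf and to the root of
#' every extra subtree of either source tree. Its restriction to either
#' source leaf set is a contraction of that source tree, and it already
#' attains the maximum possible p2 score (every bipartition with a side
#' disjoint from X survives inside its intact extra subtree).
#'
#' @param ctx an `rfs_context`
#' @return an `rfs_tree` on the union of the two source leaf sets
#' @export
build_initial_tree <- function(ctx) {
  rfs_init_state(ctx)$tree
}

# per-source extras behind `key`, ordered along the source path starting
# from the `from_side` labels
star_extras_oriented <- function(ctx, key, from_side) {
  s <- split_from_key(key)
  out <- integer(0)
  for (i in 1:2) {
    d <- ctx_decomp(ctx, i)
    if (!(key %in% names(d$edge_of))) next
    gids <- edge_extras_gid(ctx, i, d$edge_of[[key]])
    if (!setequal(from_side, s$side_a)) gids <- rev(gids)
    out <- c(out, gids)
  }
  out
}

#' Place extra subtrees behind the trivial bipartitions
#'
#' For every trivial bipartition `[x | X - x]`, the extra subtrees attached
#' along its pendant source paths are moved from the hub onto the pendant
#' edge of `x`, in path order starting nearest `x` (source-1 extras first).
#' After this step p1 equals w*(Triv): every source bipartition induced by a
#' pendant-path edge is realized in the supertree's restrictions.
#'
#' @param state an `rfs_state` fresh from the initial construction
#' @return the updated `rfs_state`
#' @export
add_trivial_bipartitions <- function(state) {
  ctx <- state$ctx
  tree <- state$tree
  for (key in ctx$triv) {
    s <- split_from_key(key)
    xlab <- if (length(s$side_a) == 1L) s$side_a else s$side_b
    gids <- star_extras_oriented(ctx, key, from_side = xlab)
    if (!length(gids)) next
    xn <- which(!is.na(tree$label) & tree$label == xlab)
    hub <- tree$adj[[xn]][1L]
    tree <- tree_remove_edge(tree, xn, hub)
    prev <- xn
    for (gid in gids) {
      r <- state$extra_node[gid]
      tree <- tree_remove_edge(tree, hub, r)
      tree <- tree_add_node(tree)
      u <- n_nodes(tree)
      tree <- tree_add_edge(tree, prev, u)
      tree <- tree_add_edge(tree, u, r)
      prev <- u
    }
    tree <- tree_add_edge(tree, prev, hub)
  }
  state$tree <- tree
  state
}

#' Refine the supertree with one non-trivial backbone bipartition
#'
#' Splits the vertex recorded in `sv` into an edge inducing `p` on X,
#' partitions its neighbours by side, subdivides the new edge with the extra
#' subtrees behind `p` (in path order), reattaches the extra subtrees on the
#' side of either part, and updates the `H`/`sv` bookkeeping (pending
#' bipartitions incompatible with `p` are discarded; compatible ones are
#' reassigned by side containment). The p1 score rises by exactly `w*(p)`;
#' p2 is unchanged.
#'
#' @param state an `rfs_state`
#' @param p an `rfs_split` of X or its canonical key; must be pending
#'   (present in `sv`)
#' @param validate check the preconditions against the current restriction
#'   (adds a restriction computation per call)
#' @return the updated `rfs_state`
#' @export
refine_with_bipartition <- function(state, p, validate = TRUE) {
  ctx <- state$ctx
  key <- if (is.character(p)) p else p$key
  if (validate) {
    cur <- names(bipartitions(restrict_tree(state$tree, ctx$x)))
    if (key %in% cur) stop("bipartition already present in the restriction: ", key)
    s0 <- split_from_key(key)
    ok <- all(vapply(cur, function(k) {
      s2 <- split_from_key(k)
      sides_compatible(s0$side_a, s0$side_b, s2$side_a, s2$side_b)
    }, TRUE))
    if (!ok) stop("bipartition incompatible with the current restriction: ", key)
  }
  if (!(key %in% names(state$sv))) {
    stop("bipartition is not pending (no split vertex recorded): ", key)
  }
  v <- state$sv[[key]]
  s <- split_from_key(key)
  A <- s$side_a
  B <- s$side_b
  tree <- state$tree

  nb <- tree$adj[[v]]
  cls <- vapply(nb, function(u) {
    xl <- reachable_labels(tree, from = u, avoid = v, within = ctx$x)
    if (!length(xl)) return("other")
    if (all(xl %in% A)) return("A")
    if (all(xl %in% B)) return("B")
    "mixed"
  }, "")
  if (any(cls == "mixed")) {
    stop("refinement invariant violated: a neighbour of the split vertex ",
         "reaches both sides of ", key)
  }

  v_a <- v
  tree <- tree_add_node(tree)
  v_b <- n_nodes(tree)
  for (u in nb[cls == "B"]) {
    tree <- tree_remove_edge(tree, v_a, u)
    tree <- tree_add_edge(tree, v_b, u)
  }

  star_ids <- star_extras_oriented(ctx, key, from_side = A)
  trsA <- trs_side(ctx, A)
  trsB <- trs_side(ctx, B)
  other_nodes <- nb[cls == "other"]
  other_gids <- unname(state$node_extra[as.character(other_nodes)])
  if (!all(star_ids %in% other_gids)) {
    stop("refinement invariant violated: an extra subtree behind ", key,
         " is not adjacent to the split vertex")
  }
  for (j in seq_along(other_nodes)) {
    gid <- other_gids[j]
    if (gid %in% star_ids) next             # placed on the new edge below
    if (gid %in% trsB) {
      tree <- tree_remove_edge(tree, v_a, other_nodes[j])
      tree <- tree_add_edge(tree, v_b, other_nodes[j])
    }
    # trsA and unconstrained extras stay at v_a
  }
  # subdivide (v_a, v_b) with the extras behind p, nearest-A first
  prev <- v_a
  for (gid in star_ids) {
    r <- state$extra_node[gid]
    tree <- tree_remove_edge(tree, v_a, r)
    tree <- tree_add_node(tree)
    u <- n_nodes(tree)
    tree <- tree_add_edge(tree, prev, u)
    tree <- tree_add_edge(tree, u, r)
    prev <- u
  }
  tree <- tree_add_edge(tree, prev, v_b)

  # update H and sv
  pend <- setdiff(state$h[[as.character(v)]], key)
  sv <- state$sv[setdiff(names(state$sv), key)]
  ha <- character(0)
  hb <- character(0)
  for (k2 in pend) {
    s2 <- split_from_key(k2)
    if (!sides_compatible(A, B, s2$side_a, s2$side_b)) {
      sv <- sv[setdiff(names(sv), k2)]
      next
    }
    if (all(s2$side_a %in% A) || all(s2$side_b %in% A)) {
      ha <- c(ha, k2)
      sv[k2] <- v_a
    } else {
      hb <- c(hb, k2)
      sv[k2] <- v_b
    }
  }
  state$h[[as.character(v_a)]] <- ha
  state$h[[as.character(v_b)]] <- hb
  state$sv <- sv
  state$tree <- tree
  state
}

#' Arbitrarily resolve a tree to binary
#'
#' Repeatedly splits every internal node of degree greater than three by
#' pulling off two randomly chosen neighbours, until the tree is fully
#' resolved. Deterministic for a fixed seed; a binary input is returned
#' unchanged (up to node renumbering). Refining never removes bipartitions,
#' so no split-support score can decrease.
#'
#' @param t an `rfs_tree`
#' @param seed integer seed controlling the arbitrary choices
#' @return a binary `rfs_tree` whose bipartition set contains `C(t)`
#' @export
resolve_to_binary <- function(t, seed = 1L) {
  t <- canonical_tree(t)
  adj <- t$adj
  label <- t$label
  withr::with_seed(as.integer(seed), {
    repeat {
      deg <- lengths(adj)
      vs <- which(is.na(label) & deg > 3L)
      if (!length(vs)) break
      v <- vs[1L]
      pick <- sample(adj[[v]], 2L)
      for (u in pick) {
        adj[[u]] <- setdiff(adj[[u]], v)
        adj[[v]] <- setdiff(adj[[v]], u)
      }
      adj[[length(adj) + 1L]] <- c(pick, v)
      label <- c(label, NA_character_)
      z <- length(adj)
      for (u in pick) adj[[u]] <- c(adj[[u]], z)
      adj[[v]] <- c(adj[[v]], z)
    }
  })
  out <- new_rfs_tree(adj, label)
  stopifnot(is_binary_tree(out))
  out
}

name_offending_vertex <- function(t, who) {
  deg <- tree_degree(t)
  bad <- which(is.na(t$label) & deg != 3L)
  stop(who, " must be binary; internal vertex ", bad[1L],
       " has degree ", deg[bad[1L]])
}

#' Exact Robinson-Foulds / Split-Fit supertree of two binary trees
#'
#' Computes a supertree on the union of the two leaf sets minimizing the
#' total Robinson-Foulds distance to the inputs (equivalently, maximizing
#' the total split support) over all binary trees on the union, in
#' polynomial time. With `relax = TRUE` the possibly multifurcating tree
#' obtained before the final arbitrary resolution is returned; it is optimal
#' for the relaxed (not-necessarily-binary) split-fit problem.
#'
#' With fewer than four shared leaves no non-trivial backbone bipartition
#' exists and the incompatibility-graph phase is skipped; with fewer than
#' three shared leaves any binary supertree consistent with the trivial
#' structure is optimal (pairwise scores on such overlaps are degenerate).
#'
#' @param t1,t2 binary `rfs_tree` source trees with at least one shared leaf
#' @param seed integer seed for the arbitrary resolution step
#' @param relax return the unresolved optimum of the relaxed problem?
#' @param check_invariants re-verify the refinement-state invariants after
#'   every refinement step (slow; intended for debugging)
#' @return list with `tree` (the supertree) and `report`
#'   (a `rfs_score_report` against the two sources)
#' @export
exact_rfs_2 <- function(t1, t2, seed = 1L, relax = FALSE,
                        check_invariants = FALSE) {
  stopifnot(inherits(t1, "rfs_tree"), inherits(t2, "rfs_tree"))
  if (!is_binary_tree(t1)) name_offending_vertex(t1, "first source tree")
  if (!is_binary_tree(t2)) name_offending_vertex(t2, "second source tree")
  x <- shared_leaves(t1, t2)
  if (!length(x)) stop("source trees share no leaves")
  if (length(x) == 1L) {
    tstar <- merge_on_single_leaf(t1, t2, x)
  } else {
    ctx <- rfs_context(t1, t2)
    st <- rfs_init_state(ctx)
    st <- add_trivial_bipartitions(st)
    if (check_invariants) check_state_invariants(st)
    if (length(ctx$nontriv)) {
      g <- build_graph(ctx)
      sel <- max_weight_independent_set(g)
      i_set <- selected_splits(g, sel)
      for (key in sort(intersect(i_set, ctx$nontriv))) {
        st <- refine_with_bipartition(st, key, validate = check_invariants)
        if (check_invariants) check_state_invariants(st)
      }
    }
    tstar <- canonical_tree(st$tree)
  }
  out <- if (relax) tstar else resolve_to_binary(tstar, seed)
  list(tree = out, report = profile_scores(out, list(t1, t2)))
}

# Supertree for a single shared leaf: hub adjacent to the shared leaf and to
# what remains of each source tree after detaching that leaf. Pairwise
# scores against any supertree are degenerate here, so any consistent
# binary tree is optimal.
merge_on_single_leaf <- function(t1, t2, x) {
  adj <- list(integer(0))
  label <- NA_character_
  hub <- 1L
  glue <- function(src) {
    xn <- which(!is.na(src$label) & src$label == x)
    keepv <- setdiff(seq_len(n_nodes(src)), xn)
    if (!length(keepv)) return(NULL)
    base <- length(adj)
    map <- integer(n_nodes(src))
    map[keepv] <- base + seq_along(keepv)
    for (v in keepv) adj[[map[v]]] <<- integer(0)
    label <<- c(label, src$label[keepv])
    for (v in keepv) {
      for (u in src$adj[[v]]) {
        if (u %in% keepv && v < u) {
          adj[[map[v]]] <<- c(adj[[map[v]]], map[u])
          adj[[map[u]]] <<- c(adj[[map[u]]], map[v])
        }
      }
    }
    root <- if (length(src$adj[[xn]])) map[src$adj[[xn]][1L]] else map[keepv[1L]]
    adj[[hub]] <<- c(adj[[hub]], root)
    adj[[root]] <<- c(adj[[root]], hub)
    NULL
  }
  glue(t1)
  glue(t2)
  adj[[hub]] <- c(adj[[hub]], length(adj) + 1L)
  adj[[length(adj) + 1L]] <- hub
  label <- c(label, x)
  canonical_tree(new_rfs_tree(adj, label, validate = FALSE))
}

#' Verify the refinement-state invariants
#'
#' Re-derives, from scratch, the three invariants maintained by the
#' refinement bookkeeping: (1) every pending bipartition's recorded split
#' vertex is the unique vertex whose refinement inserts it into the
#' restriction; (2) every extra subtree behind a pending bipartition is
#' rooted at a neighbour of its split vertex; (3) for every bipartition
#' `[A|B]` of the current restriction, the extra subtrees on the side of A
#' attach strictly within the A-side component (and symmetrically for B).
#' Throws on the first violation.
#'
#' @param state an `rfs_state`
#' @return `TRUE`, invisibly
#' @export
check_state_invariants <- function(state) {
  ctx <- state$ctx
  tree <- state$tree
  cur <- names(bipartitions(restrict_tree(tree, ctx$x)))

  # pending set must be exactly the addable non-trivial backbone splits
  addable <- setdiff(ctx$nontriv, cur)
  addable <- addable[vapply(addable, function(k) {
    s <- split_from_key(k)
    all(vapply(cur, function(k2) {
      s2 <- split_from_key(k2)
      sides_compatible(s$side_a, s$side_b, s2$side_a, s2$side_b)
    }, TRUE))
  }, TRUE)]
  if (!setequal(addable, names(state$sv))) {
    stop("sv bookkeeping out of sync with the addable bipartitions")
  }

  for (key in names(state$sv)) {
    v <- state$sv[[key]]
    s <- split_from_key(key)
    # (1) v separates A from B: no neighbour component mixes the sides
    for (u in tree$adj[[v]]) {
      xl <- reachable_labels(tree, from = u, avoid = v, within = ctx$x)
      if (length(intersect(xl, s$side_a)) && length(intersect(xl, s$side_b))) {
        stop("invariant 1 violated for ", key)
      }
    }
    # (2) extras behind key adjacent to v
    for (gid in tr_star(ctx, key)) {
      if (!(v %in% tree$adj[[state$extra_node[gid]]])) {
        stop("invariant 2 violated for ", key)
      }
    }
  }

  # (3) side placement of extras for every realized bipartition
  em <- tree_edges(tree)
  for (key in cur) {
    s <- split_from_key(key)
    on_path <- logical(nrow(em))
    for (r in seq_len(nrow(em))) {
      xl <- reachable_labels(tree, from = em[r, 2L], avoid = em[r, 1L],
                             within = ctx$x)
      on_path[r] <- setequal(xl, s$side_a) || setequal(xl, s$side_b)
    }
    comp_of <- function(side) {
      start <- which(!is.na(tree$label) & tree$label == side[1L])
      seen <- rep(FALSE, n_nodes(tree))
      seen[start] <- TRUE
      stack <- start
      while (length(stack)) {
        v <- stack[length(stack)]
        stack <- stack[-length(stack)]
        for (u in tree$adj[[v]]) {
          blocked <- any(on_path &
                           ((em[, 1L] == v & em[, 2L] == u) |
                              (em[, 1L] == u & em[, 2L] == v)))
          if (!blocked && !seen[u]) {
            seen[u] <- TRUE
            stack <- c(stack, u)
          }
        }
      }
      which(seen)
    }
    compA <- comp_of(s$side_a)
    compB <- comp_of(s$side_b)
    for (gid in trs_side(ctx, s$side_a)) {
      if (!all(state$extra_nodes[[gid]] %in% compA)) {
        stop("invariant 3 violated for ", key, " (side A)")
      }
    }
    for (gid in trs_side(ctx, s$side_b)) {
      if (!all(state$extra_nodes[[gid]] %in% compB)) {
        stop("invariant 3 violated for ", key, " (side B)")
      }
    }
  }
  invisible(TRUE)
}
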