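# Backbone decomposition of a source tree around the shared leaf set X.
#
# Restricting a source tree T_i to X gives the backbone tree T_i|_X. Each
# backbone edge e corresponds to a path P(e) in T_i whose internal vertices
# were suppressed; w(e) = |P(e)| counts the edges of that path. Deleting the
# spanning subtree of X from T_i leaves rooted "extra subtrees", each
# attached either to an internal vertex of some P(e) (recorded in TR(e), in
# path order) or directly at a backbone vertex (possible only when the
# source tree is multifurcating).

backbone_decomp_impl <- function(source, x) {
  x <- sort(unique(as.character(x)))
  missing <- setdiff(x, tree_labels(source))
  if (length(missing)) stop("shared leaves not in tree: ", paste(missing, collapse = ", "))
  if (length(x) < 2L) stop("backbone decomposition needs at least 2 shared leaves")
  n <- n_nodes(source)
  adj <- source$adj
  label <- source$label
  wanted <- !is.na(label) & label %in% x

  # minimal spanning subtree of x: iteratively shed degree-<=1 nodes not in x
  keep <- rep(TRUE, n)
  radj <- adj
  repeat {
    deg <- integer(n)
    deg[keep] <- lengths(radj[keep])
    drop <- which(keep & !wanted & deg <= 1L)
    if (!length(drop)) break
    for (v in drop) {
      for (u in radj[[v]]) radj[[u]] <- setdiff(radj[[u]], v)
      radj[[v]] <- integer(0)
      keep[v] <- FALSE
    }
  }
  degR <- integer(n)
  degR[keep] <- lengths(radj[keep])
  important <- keep & (wanted | degR >= 3L)

  # backbone nodes: important vertices, renumbered in source-id order
  imp <- which(important)
  bnode_of <- integer(n)
  bnode_of[imp] <- seq_along(imp)

  # walk maximal paths between important vertices through degree-2 vertices
  edges <- list()
  visited_half <- character(0)
  for (u in imp) {
    for (w0 in radj[[u]]) {
      half <- paste(u, w0)
      if (half %in% visited_half) next
      path <- c(u, w0)
      prev <- u
      w <- w0
      while (!important[w]) {
        nxt <- setdiff(radj[[w]], prev)
        stopifnot(length(nxt) == 1L)
        prev <- w
        w <- nxt
        path <- c(path, w)
      }
      visited_half <- c(visited_half, half, paste(w, path[length(path) - 1L]))
      edges[[length(edges) + 1L]] <- list(path = path)
    }
  }

  # backbone tree
  badj <- vector("list", length(imp))
  for (e in edges) {
    a <- bnode_of[e$path[1L]]
    b <- bnode_of[e$path[length(e$path)]]
    badj[[a]] <- c(badj[[a]], b)
    badj[[b]] <- c(badj[[b]], a)
  }
  blabel <- label[imp]
  blabel[!(blabel %in% x)] <- NA_character_
  backbone <- new_rfs_tree(badj, blabel, validate = length(imp) > 1L)

  # extra subtrees: components of source minus the spanning subtree
  extras <- list()
  attach_of <- integer(0)  # source node -> extra id (roots only)
  for (v in which(keep)) {
    for (u in adj[[v]]) {
      if (keep[u]) next
      nodes <- integer(0)
      stack <- u
      seen <- rep(FALSE, n)
      seen[v] <- TRUE
      seen[u] <- TRUE
      while (length(stack)) {
        z <- stack[length(stack)]
        stack <- stack[-length(stack)]
        nodes <- c(nodes, z)
        for (y in adj[[z]]) if (!seen[y]) { seen[y] <- TRUE; stack <- c(stack, y) }
      }
      extras[[length(extras) + 1L]] <- list(
        id = length(extras) + 1L,
        root_src = u,
        attach_src = v,
        nodes_src = nodes,
        leaves = sort(label[nodes][!is.na(label[nodes])])
      )
    }
  }

  # locate each extra: on a path (edge-attached) or at a backbone vertex
  path_pos <- vector("list", length(edges))
  on_edge <- integer(n); pos_on_edge <- integer(n)
  for (k in seq_along(edges)) {
    p <- edges[[k]]$path
    inner <- p[-c(1L, length(p))]
    on_edge[inner] <- k
    pos_on_edge[inner] <- seq_along(inner) + 1L  # index within path vector
  }
  for (k in seq_along(extras)) {
    a <- extras[[k]]$attach_src
    if (important[a]) {
      extras[[k]]$attach_type <- "vertex"
      extras[[k]]$attach_edge <- NA_integer_
      extras[[k]]$attach_pos <- NA_integer_
      extras[[k]]$attach_bvertex <- bnode_of[a]
    } else {
      extras[[k]]$attach_type <- "edge"
      extras[[k]]$attach_edge <- on_edge[a]
      extras[[k]]$attach_pos <- pos_on_edge[a]
      extras[[k]]$attach_bvertex <- NA_integer_
    }
  }

  # per-edge split keys, canonical orientation, weights, attached extras
  edge_of <- integer(0)
  for (k in seq_along(edges)) {
    p <- edges[[k]]$path
    bu <- bnode_of[p[1L]]
    bv <- bnode_of[p[length(p)]]
    if (length(imp) == 2L) {
      side_u <- backbone$label[bu]
      side_v <- backbone$label[bv]
    } else {
      side_v <- reachable_labels(backbone, from = bv, avoid = bu)
      side_u <- setdiff(x, side_v)
    }
    s <- make_split(side_u, side_v)
    # orient the stored path from the canonical side_a endpoint
    if (!(side_u[1L] %in% s$side_a)) {
      p <- rev(p)
      edges[[k]]$path <- p
      # re-index attachment positions of extras on this edge
      for (j in seq_along(extras)) {
        if (identical(extras[[j]]$attach_edge, k)) {
          extras[[j]]$attach_pos <- length(p) + 1L - extras[[j]]$attach_pos
        }
      }
    }
    edges[[k]]$key <- s$key
    edges[[k]]$split <- s
    edges[[k]]$w <- length(p) - 1L
    ex_here <- which(vapply(extras, function(e) identical(e$attach_edge, k), TRUE))
    if (length(ex_here)) {
      ord <- order(vapply(extras[ex_here], `[[`, 0L, "attach_pos"),
                   vapply(extras[ex_here], `[[`, 0L, "root_src"))
      ex_here <- ex_here[ord]
    }
    edges[[k]]$extras <- ex_here
    edge_of[s$key] <- k
  }

  structure(list(source = source, x = x, backbone = backbone,
                 bnode_src = imp, edges = edges, edge_of = edge_of,
                 extras = extras),
            class = "rfs_backbone")
}

#' Backbone decomposition of a source tree
#'
#' Computes the backbone tree (the source restricted to the shared leaf set
#' `x`), the source path and weight behind every backbone edge, the extra
#' subtrees hanging off those paths (in path order), and the map from every
#' backbone bipartition to its inducing edge.
#'
#' @param source an `rfs_tree`
#' @param x character vector of shared leaf labels, `length(x) >= 3`,
#'   a subset of `tree_labels(source)`
#' @return an `rfs_backbone` object
#' @export
compute_backbone <- function(source, x) {
  if (length(unique(x)) < 3L) {
    stop("backbone decomposition requires at least 3 shared leaves")
  }
  backbone_decomp_impl(source, x)
}

#' @export
print.rfs_backbone <- function(x, ...) {
  cat("backbone decomposition on", length(x$x), "shared leaves;",
      length(x$edges), "backbone edges,", length(x$extras), "extra subtrees\n")
  for (k in seq_along(x$edges)) {
    e <- x$edges[[k]]
    cat(sprintf("  e%d  w=%d  [%s]  extras: %s\n", k, e$w, e$key,
                if (length(e$extras)) paste(e$extras, collapse = ",") else "-"))
  }
  invisible(x)
}

#' Shared context for a pair of source trees
#'
#' Builds both backbone decompositions around the shared leaf set X plus the
#' derived sets used throughout the supertree construction: the trivial and
#' non-trivial backbone bipartitions, the partition of all source-tree
#' bipartitions into those meeting X on both sides and the rest, and the
#' maximum-gain weight w* of every backbone bipartition.
#'
#' @param t1,t2 `rfs_tree` source trees with at least two shared leaves
#' @return an `rfs_context` object
#' @export
rfs_context <- function(t1, t2) {
  x <- shared_leaves(t1, t2)
  if (length(x) < 2L) stop("shared context requires at least 2 shared leaves")
  d1 <- backbone_decomp_impl(t1, x)
  d2 <- backbone_decomp_impl(t2, x)
  c1x <- names(d1$edge_of)
  c2x <- names(d2$edge_of)
  cx <- union(c1x, c2x)
  trivial <- vapply(cx, is_trivial_split, TRUE)

  w1 <- stats::setNames(rep(0L, length(cx)), cx)
  w2 <- w1
  w1[c1x] <- vapply(d1$edges[d1$edge_of[c1x]], `[[`, 0L, "w")
  w2[c2x] <- vapply(d2$edges[d2$edge_of[c2x]], `[[`, 0L, "w")

  classify <- function(tree) {
    sp <- bipartitions(tree)
    both <- vapply(sp, function(s) {
      length(intersect(s$side_a, x)) > 0L && length(intersect(s$side_b, x)) > 0L
    }, TRUE)
    list(pi1 = names(sp)[both], pi2 = names(sp)[!both])
  }
  k1 <- classify(t1)
  k2 <- classify(t2)

  # global extra-subtree ids: source 1 extras first, then source 2
  m1 <- length(d1$extras)
  extras <- c(
    lapply(d1$extras, function(e) c(e, list(source = 1L, gid = e$id))),
    lapply(d2$extras, function(e) c(e, list(source = 2L, gid = e$id + m1)))
  )

  structure(list(t1 = t1, t2 = t2, x = x, d1 = d1, d2 = d2,
                 s1 = tree_labels(t1), s2 = tree_labels(t2),
                 c1x = c1x, c2x = c2x, cx = cx,
                 triv = cx[trivial], nontriv = cx[!trivial],
                 pi1 = list(k1$pi1, k2$pi1), pi2 = list(k1$pi2, k2$pi2),
                 w1 = w1, w2 = w2, wstar = w1 + w2,
                 extras = extras, gid_offset = c(0L, m1)),
            class = "rfs_context")
}

#' @export
print.rfs_context <- function(x, ...) {
  cat("shared context: |X| =", length(x$x),
      "; backbone splits:", length(x$cx),
      "(", length(x$nontriv), "non-trivial );",
      length(x$extras), "extra subtrees\n")
  invisible(x)
}

ctx_decomp <- function(ctx, i) if (i == 1L) ctx$d1 else ctx$d2

# global ids of extras attached to backbone edge `edge_idx` of source i,
# in stored (canonical side_a -> side_b) path order
edge_extras_gid <- function(ctx, i, edge_idx) {
  d <- ctx_decomp(ctx, i)
  d$edges[[edge_idx]]$extras + ctx$gid_offset[i]
}

#' Extra subtrees behind a backbone bipartition
#'
#' The union, over the source trees whose backbone contains `p`, of the
#' extra subtrees attached to the inducing edge's path. Returns ids into
#' `ctx$extras`, source-1 extras first, each source's extras in path order
#' oriented from the bipartition's canonical first side. A bipartition
#' absent from both backbones yields an empty set (mirroring w* = 0).
#'
#' @param ctx an `rfs_context`
#' @param p an `rfs_split` on X, or its canonical key
#' @return integer vector of extra-subtree ids
#' @export
tr_star <- function(ctx, p) {
  key <- if (is.character(p)) p else p$key
  out <- integer(0)
  for (i in 1:2) {
    d <- ctx_decomp(ctx, i)
    if (key %in% names(d$edge_of)) {
      out <- c(out, edge_extras_gid(ctx, i, d$edge_of[[key]]))
    }
  }
  out
}

#' Backbone bipartitions on the side of a leaf subset
#'
#' Returns the bipartitions of a backbone tree with one side a strict subset
#' of `q`: the splits "on the side of q", i.e. exactly those compatible with
#' any bipartition having q as one side.
#'
#' @param ctx an `rfs_context`
#' @param q character vector, a subset of the shared leaf set X
#' @param which `"both"`, `1`, or `2`: which backbone(s) to draw from
#' @return character vector of canonical split keys
#' @export
bp_side <- function(ctx, q, which = "both") {
  q <- as.character(q)
  if (length(setdiff(q, ctx$x))) stop("q must be a subset of the shared leaf set")
  pick <- function(i) {
    d <- ctx_decomp(ctx, i)
    keys <- names(d$edge_of)
    keep <- vapply(keys, function(k) {
      s <- d$edges[[d$edge_of[[k]]]]$split
      (all(s$side_a %in% q) && length(s$side_a) < length(q)) ||
        (all(s$side_b %in% q) && length(s$side_b) < length(q))
    }, TRUE)
    keys[keep]
  }
  if (identical(which, "both")) union(pick(1L), pick(2L)) else pick(as.integer(which))
}

#' Extra subtrees on the side of a leaf subset
#'
#' Maps [bp_side()] through the edge-attachment sets: the union of TR(e)
#' over the backbone edges whose bipartitions lie on the side of `q`.
#'
#' @inheritParams bp_side
#' @return integer vector of extra-subtree ids
#' @export
trs_side <- function(ctx, q, which = "both") {
  idx <- if (identical(which, "both")) 1:2 else as.integer(which)
  out <- integer(0)
  for (i in idx) {
    d <- ctx_decomp(ctx, i)
    for (k in bp_side(ctx, q, which = i)) {
      out <- c(out, edge_extras_gid(ctx, i, d$edge_of[[k]]))
    }
  }
  sort(unique(out))
}

#' Partition of source-tree bipartitions by the shared leaf set
#'
#' Splits the union of the two source trees' bipartition sets into those
#' whose both sides intersect X (induced by edges on the minimal spanning
#' subtrees of X) and the rest (induced inside or just above extra
#' subtrees).
#'
#' @param ctx an `rfs_context`
#' @return list with character-key vectors `pi1` and `pi2`
#' @export
split_pi <- function(ctx) {
  list(pi1 = c(ctx$pi1[[1]], ctx$pi1[[2]]),
       pi2 = c(ctx$pi2[[1]], ctx$pi2[[2]]))
}

#' Maximum potential split-support gain of backbone bipartitions
#'
#' For a bipartition of X, w* is 0 when it occurs in neither backbone, the
#' weight of its inducing edge when it occurs in one, and the sum of the two
#' edge weights when it occurs in both; extended additively over sets.
#'
#' @param ctx an `rfs_context`
#' @param p an `rfs_split`, a canonical key, or a vector of keys
#' @return non-negative integer
#' @export
w_star <- function(ctx, p) {
  keys <- if (is.character(p)) p else p$key
  present <- keys[keys %in% names(ctx$wstar)]
  if (!length(present)) return(0L)
  as.integer(sum(ctx$wstar[present]))
}

#' Split-support decomposition of a supertree
#'
#' Decomposes the split support score of `t` against the two source trees
#' into `p1` (contributed by bipartitions meeting X on both sides) and `p2`
#' (the rest); `p1 + p2` equals the total split support.
#'
#' @param ctx an `rfs_context`
#' @param t an `rfs_tree` on the union of the source leaf sets
#' @return list with integers `p1` and `p2`
#' @export
p_scores <- function(ctx, t) {
  labs <- tree_labels(t)
  if (!setequal(labs, union(ctx$s1, ctx$s2))) {
    stop("supertree leaf set must equal the union of the source leaf sets")
  }
  p1 <- 0L; p2 <- 0L
  for (i in 1:2) {
    si <- if (i == 1L) ctx$s1 else ctx$s2
    src <- if (i == 1L) ctx$t1 else ctx$t2
    shared <- intersect(names(bipartitions(restrict_tree(t, si))),
                        names(bipartitions(src)))
    p1 <- p1 + length(intersect(shared, ctx$pi1[[i]]))
    p2 <- p2 + length(intersect(shared, ctx$pi2[[i]]))
  }
  list(p1 = p1, p2 = p2)
}
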