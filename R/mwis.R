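# Weighted incompatibility graph of the two backbone trees, and
# maximum-weight independent set extraction.
#
# One vertex per bipartition occurrence (a split present in both backbones
# yields two vertices, each with its own weight w(e_i)); edges join
# incompatible pairs. Splits of a common tree are mutually compatible, so
# the graph is bipartite by source index, and MWIS reduces to min-cut:
# source -> side-1 vertices with capacity = weight, side-2 vertices -> sink
# with capacity = weight, incompatibility edges with effectively infinite
# capacity; the MWIS is the complement of the min vertex cover read off the
# cut.

#' Weighted incompatibility graph of the two backbones
#'
#' @param ctx an `rfs_context`
#' @return an `rfs_incompat_graph`: list with `vertices` (data.frame with
#'   columns key, source, weight) and `edges` (two-column integer matrix of
#'   vertex indices)
#' @export
build_graph <- function(ctx) {
  vkey <- c(ctx$c1x, ctx$c2x)
  vsrc <- rep(1:2, c(length(ctx$c1x), length(ctx$c2x)))
  vw <- integer(length(vkey))
  vw[vsrc == 1L] <- as.integer(ctx$w1[ctx$c1x])
  vw[vsrc == 2L] <- as.integer(ctx$w2[ctx$c2x])
  splits <- lapply(vkey, split_from_key)
  edges <- matrix(integer(0), ncol = 2)
  i1 <- which(vsrc == 1L)
  i2 <- which(vsrc == 2L)
  for (a in i1) {
    for (b in i2) {
      sa <- splits[[a]]; sb <- splits[[b]]
      if (!sides_compatible(sa$side_a, sa$side_b, sb$side_a, sb$side_b)) {
        edges <- rbind(edges, c(a, b))
      }
    }
  }
  structure(list(vertices = data.frame(key = vkey, source = vsrc,
                                       weight = vw,
                                       stringsAsFactors = FALSE),
                 edges = edges),
            class = "rfs_incompat_graph")
}

#' @export
print.rfs_incompat_graph <- function(x, ...) {
  cat("incompatibility graph:", nrow(x$vertices), "vertices,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

graph_check_bipartite <- function(g) {
  if (nrow(g$edges)) {
    src <- g$vertices$source
    if (any(src[g$edges[, 1L]] == src[g$edges[, 2L]])) {
      stop("incompatibility graph is not bipartite by source index; ",
           "splits of a common tree should be mutually compatible")
    }
  }
  invisible(g)
}

#' Maximum-weight independent set of a bipartite incompatibility graph
#'
#' Solved exactly by the max-flow/min-cut reduction; all isolated vertices
#' (shared and trivial bipartitions) are always in the optimum. Vertices are
#' processed in their canonical order, so the selected optimum is
#' deterministic.
#'
#' @param g an `rfs_incompat_graph`
#' @return integer vector of selected vertex indices
#' @export
max_weight_independent_set <- function(g) {
  graph_check_bipartite(g)
  nv <- nrow(g$vertices)
  if (nv == 0L) return(integer(0))
  if (!nrow(g$edges)) return(seq_len(nv))
  isolated <- setdiff(seq_len(nv), unique(as.integer(g$edges)))
  s <- nv + 1L
  t <- nv + 2L
  inf <- sum(g$vertices$weight) + 1
  i1 <- which(g$vertices$source == 1L)
  i2 <- which(g$vertices$source == 2L)
  el <- rbind(cbind(s, i1), cbind(i2, t), g$edges)
  caps <- c(g$vertices$weight[i1], g$vertices$weight[i2],
            rep(inf, nrow(g$edges)))
  gr <- igraph::graph_from_edgelist(el, directed = TRUE)
  mf <- igraph::max_flow(gr, source = s, target = t, capacity = caps)
  p1 <- as.integer(mf$partition1)  # side containing the flow source
  if (!(s %in% p1)) p1 <- as.integer(mf$partition2)
  cover <- c(setdiff(i1, p1), intersect(i2, p1))
  sel <- sort(union(setdiff(seq_len(nv), cover), isolated))
  # sanity: complement of a min cut of value mf$value
  stopifnot(sum(g$vertices$weight[sel]) == sum(g$vertices$weight) - mf$value)
  sel
}

#' Bipartitions selected by an independent set
#'
#' De-duplicates the bipartitions behind a set of independent vertices (a
#' split occurring in both backbones is selected once). The result is
#' pairwise compatible and contains every split common to the two
#' backbones, since those vertices are isolated.
#'
#' @param g an `rfs_incompat_graph`
#' @param ids integer vector of vertex indices, independent in `g`
#' @return character vector of canonical split keys, sorted
#' @export
selected_splits <- function(g, ids) {
  if (nrow(g$edges)) {
    inset <- logical(nrow(g$vertices))
    inset[ids] <- TRUE
    if (any(inset[g$edges[, 1L]] & inset[g$edges[, 2L]])) {
      stop("vertex set is not independent in the incompatibility graph")
    }
  }
  sort(unique(g$vertices$key[ids]))
}
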