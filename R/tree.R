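#' @keywords internal
"_PACKAGE"

# Unrooted leaf-labelled tree, stored as an adjacency list.
#
# Fields:
#   adj   - list of integer vectors; adj[[v]] are the neighbours of node v
#   label - character vector; label[v] is the leaf label of v, NA for
#           internal nodes
#
# Invariants (enforced by tree_validate): connected, |E| = |V| - 1, leaf
# labels unique, every labelled node has degree <= 1 (degree 0 only for the
# single-leaf tree), every unlabelled node has degree >= 3.

new_rfs_tree <- function(adj, label, validate = TRUE) {
  t <- structure(list(adj = adj, label = as.character(label)),
                 class = "rfs_tree")
  if (validate) tree_validate(t)
  t
}

#' Number of nodes in a tree
#' @param t an `rfs_tree`
#' @return integer node count
#' @export
n_nodes <- function(t) length(t$adj)

#' Leaf labels of a tree
#' @param t an `rfs_tree`
#' @return sorted character vector of leaf labels
#' @export
tree_labels <- function(t) sort(t$label[!is.na(t$label)])

tree_leaf_nodes <- function(t) which(!is.na(t$label))

tree_degree <- function(t) lengths(t$adj)

#' Edges of a tree
#' @param t an `rfs_tree`
#' @return two-column integer matrix, one row per edge, smaller node id first
#' @export
tree_edges <- function(t) {
  n <- n_nodes(t)
  u <- rep.int(seq_len(n), lengths(t$adj))
  v <- unlist(t$adj, use.names = FALSE)
  keep <- u < v
  cbind(u = u[keep], v = v[keep])
}

#' Test whether a tree is fully resolved (binary)
#'
#' An unrooted tree is binary when every internal node has degree exactly 3.
#' Trees with fewer than three leaves are trivially binary.
#'
#' @param t an `rfs_tree`
#' @return logical
#' @export
is_binary_tree <- function(t) {
  internal <- is.na(t$label)
  all(tree_degree(t)[internal] == 3L)
}

tree_validate <- function(t) {
  n <- length(t$adj)
  if (n == 0L) stop("empty tree")
  if (length(t$label) != n) stop("label vector length mismatch")
  deg <- tree_degree(t)
  # symmetry of adjacency
  for (v in seq_len(n)) {
    for (u in t$adj[[v]]) {
      if (!(v %in% t$adj[[u]])) stop("adjacency is not symmetric")
    }
  }
  labs <- t$label[!is.na(t$label)]
  if (anyDuplicated(labs)) {
    stop("duplicate leaf labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  if (length(labs) == 0L) stop("tree has no labelled leaves")
  nedge <- sum(deg) / 2
  if (nedge != n - 1L) stop("tree is not acyclic/connected: |E| != |V|-1")
  # connectivity
  seen <- rep(FALSE, n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (u in t$adj[[v]]) {
      if (!seen[u]) {
        seen[u] <- TRUE
        stack <- c(stack, u)
      }
    }
  }
  if (!all(seen)) stop("tree is not connected")
  leaf <- !is.na(t$label)
  if (length(labs) >= 2L && any(deg[leaf] != 1L)) {
    stop("leaves must have exactly one neighbour")
  }
  if (any(!leaf & deg < 3L)) {
    stop("internal node of degree < 3 (degree-2 nodes must be suppressed)")
  }
  invisible(t)
}

# Drop unused nodes and renumber contiguously.
compact_tree <- function(adj, label, keep) {
  idx <- which(keep)
  remap <- integer(length(keep))
  remap[idx] <- seq_along(idx)
  new_adj <- lapply(idx, function(v) remap[adj[[v]]])
  new_rfs_tree(new_adj, label[idx], validate = FALSE)
}

# Suppress all unlabelled degree-2 nodes in an adjacency list (in place on
# copies); returns list(adj, label, keep).
suppress_degree2 <- function(adj, label, keep = rep(TRUE, length(adj))) {
  repeat {
    deg <- integer(length(adj))
    deg[keep] <- lengths(adj[keep])
    cand <- which(keep & is.na(label) & deg == 2L)
    if (!length(cand)) break
    v <- cand[1L]
    nb <- adj[[v]]
    u <- nb[1L]; w <- nb[2L]
    adj[[u]] <- c(setdiff(adj[[u]], v), w)
    adj[[w]] <- c(setdiff(adj[[w]], v), u)
    adj[[v]] <- integer(0)
    keep[v] <- FALSE
  }
  list(adj = adj, label = label, keep = keep)
}

#' Parse a Newick string into an unrooted tree
#'
#' Parsing is delegated to [ape::read.tree()]; the resulting (possibly
#' rooted) tree is converted to an unrooted representation by suppressing any
#' degree-2 node introduced by the rooted Newick form. Branch lengths and
#' internal node labels are discarded: all scoring in this package is
#' topology-only.
#'
#' @param text a single Newick string (terminating `;` optional)
#' @return an `rfs_tree`
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";", text, fixed = TRUE)) text <- paste0(text, ";")
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo")) {
    stop("malformed Newick string (near character ",
         newick_error_position(text), "): ", text)
  }
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  }
  tree_from_ape(phy)
}

# Best-effort position of the first structural problem in a Newick string:
# first position where parenthesis balance goes negative, else the end.
newick_error_position <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  bal <- cumsum((chars == "(") - (chars == ")"))
  bad <- which(bal < 0)
  if (length(bad)) bad[1L] else nchar(text)
}

tree_from_ape <- function(phy) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  adj <- vector("list", nn)
  for (k in seq_len(nrow(phy$edge))) {
    a <- phy$edge[k, 1L]; b <- phy$edge[k, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  label <- c(phy$tip.label, rep(NA_character_, phy$Nnode))
  if (ntip == 1L) {
    return(new_rfs_tree(list(integer(0)), label[1L], validate = FALSE))
  }
  s <- suppress_degree2(adj, label)
  out <- compact_tree(s$adj, s$label, s$keep)
  tree_validate(out)
  out
}

#' Serialize a tree to a canonical Newick string
#'
#' The tree is written rooted at the internal node adjacent to the smallest
#' leaf label (or at that leaf's unique neighbour), and the children of every
#' node are emitted in increasing order of their smallest descendant label.
#' The output therefore depends only on the tree topology, and round-trips
#' through [parse_newick()] to an isomorphic tree.
#'
#' @param t an `rfs_tree`
#' @return a single Newick string, terminated by `;`
#' @export
write_newick <- function(t) {
  n <- n_nodes(t)
  if (n == 1L) return(paste0(t$label[1L], ";"))
  labs <- tree_labels(t)
  if (n == 2L) return(paste0("(", labs[1L], ",", labs[2L], ");"))
  leaves <- tree_leaf_nodes(t)
  first_leaf <- leaves[order(t$label[leaves])][1L]
  root <- t$adj[[first_leaf]][1L]
  emit <- function(v, parent) {
    kids <- setdiff(t$adj[[v]], parent)
    if (!length(kids)) return(list(str = t$label[v], min = t$label[v]))
    sub <- lapply(kids, emit, parent = v)
    ord <- order(vapply(sub, `[[`, "", "min"))
    sub <- sub[ord]
    str <- paste0("(", paste(vapply(sub, `[[`, "", "str"), collapse = ","), ")")
    list(str = str, min = sub[[1L]]$min)
  }
  res <- emit(root, 0L)
  paste0(res$str, ";")
}

#' @export
print.rfs_tree <- function(x, ...) {
  cat("rfs_tree with", length(tree_labels(x)), "leaves:", write_newick(x), "\n")
  invisible(x)
}

#' Restrict a tree to a subset of its leaves
#'
#' Returns the homeomorphic subtree induced by `r`: the minimal subtree
#' spanning the leaves in `r`, with all resulting degree-2 nodes suppressed.
#' The bipartition set of the result equals the set of restrictions of the
#' original bipartitions whose two sides both intersect `r`.
#'
#' @param t an `rfs_tree`
#' @param r character vector of leaf labels, a non-empty subset of
#'   `tree_labels(t)`
#' @return an `rfs_tree` with leaf set `r`
#' @export
restrict_tree <- function(t, r) {
  r <- unique(as.character(r))
  if (length(r) == 0L) stop("cannot restrict to an empty leaf set")
  missing <- setdiff(r, tree_labels(t))
  if (length(missing)) {
    stop("labels not in tree: ", paste(missing, collapse = ", "))
  }
  adj <- t$adj
  label <- t$label
  keep <- rep(TRUE, length(adj))
  wanted <- !is.na(label) & label %in% r
  # iteratively prune nodes of degree <= 1 that are not wanted leaves
  repeat {
    deg <- integer(length(adj))
    deg[keep] <- lengths(adj[keep])
    drop <- which(keep & !wanted & deg <= 1L)
    if (!length(drop)) break
    for (v in drop) {
      for (u in adj[[v]]) adj[[u]] <- setdiff(adj[[u]], v)
      adj[[v]] <- integer(0)
      keep[v] <- FALSE
    }
  }
  label[keep & !wanted] <- NA_character_   # labels outside r never survive here
  s <- suppress_degree2(adj, label, keep)
  out <- compact_tree(s$adj, s$label, s$keep)
  tree_validate(out)
  out
}

# Orient the tree from `root`; returns preorder vector and parent vector.
rooted_order <- function(t, root) {
  n <- n_nodes(t)
  parent <- integer(n)
  order <- integer(n)
  seen <- rep(FALSE, n)
  stack <- root
  seen[root] <- TRUE
  k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    order[k] <- v
    for (u in t$adj[[v]]) {
      if (!seen[u]) {
        seen[u] <- TRUE
        parent[u] <- v
        stack <- c(stack, u)
      }
    }
  }
  list(order = order, parent = parent)
}

# Leaf labels (restricted to `within`, if given) reachable from `from`
# without crossing `avoid`.
reachable_labels <- function(t, from, avoid, within = NULL) {
  seen <- rep(FALSE, n_nodes(t))
  seen[avoid] <- TRUE
  stack <- from
  seen[from] <- TRUE
  out <- character(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (!is.na(t$label[v])) out <- c(out, t$label[v])
    for (u in t$adj[[v]]) {
      if (!seen[u]) {
        seen[u] <- TRUE
        stack <- c(stack, u)
      }
    }
  }
  if (!is.null(within)) out <- intersect(out, within)
  out
}

#' Bipartitions (splits) of a tree
#'
#' Every edge of an unrooted tree induces a bipartition of the leaf set.
#' With `nontrivial_only = TRUE`, bipartitions separating a single leaf from
#' the rest (pendant edges) are dropped.
#'
#' @param t an `rfs_tree` with at least two leaves
#' @param nontrivial_only drop trivial (single-leaf) bipartitions?
#' @return a named list of `rfs_split` objects, keyed by canonical key
#' @export
bipartitions <- function(t, nontrivial_only = FALSE) {
  labs <- tree_labels(t)
  if (length(labs) < 2L) stop("bipartitions require at least two leaves")
  ro <- rooted_order(t, root = 1L)
  n <- n_nodes(t)
  desc <- vector("list", n)
  for (v in rev(ro$order)) {
    if (!is.na(t$label[v])) {
      desc[[v]] <- t$label[v]
    }
    if (ro$parent[v] != 0L) {
      p <- ro$parent[v]
      desc[[p]] <- c(desc[[p]], desc[[v]])
    }
  }
  out <- list()
  for (v in ro$order) {
    if (ro$parent[v] == 0L) next
    b <- desc[[v]]
    a <- setdiff(labs, b)
    if (nontrivial_only && (length(a) < 2L || length(b) < 2L)) next
    s <- make_split(a, b)
    out[[s$key]] <- s
  }
  out
}

# Suppress degree-2 nodes, renumber contiguously, validate.
canonical_tree <- function(t) {
  s <- suppress_degree2(t$adj, t$label)
  out <- compact_tree(s$adj, s$label, s$keep)
  tree_validate(out)
  out
}

#' Test two trees for isomorphism
#'
#' Two unrooted leaf-labelled trees on the same leaf set are isomorphic if
#' and only if they induce the same bipartition set.
#'
#' @param a,b `rfs_tree` objects
#' @return logical
#' @export
trees_isomorphic <- function(a, b) {
  la <- tree_labels(a)
  if (!identical(la, tree_labels(b))) return(FALSE)
  if (length(la) == 1L) return(TRUE)
  setequal(names(bipartitions(a)), names(bipartitions(b)))
}
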