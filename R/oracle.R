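# Brute-force references: exhaustive enumeration of unrooted binary
# topologies, exhaustive supertree search, exhaustive MWIS.
#
# The enumerators are deliberately independent of the supertree algorithm:
# trees are generated by stepwise leaf insertion and scored through split
# bitmasks, so that agreement between the exact algorithm and these oracles
# is a meaningful cross-check.

# All unrooted binary topologies on n labelled leaves, as edge matrices.
# Nodes: leaves 1..n, internal nodes n+1..2n-2. Deterministic insertion
# order (leaf 4, 5, ...), each leaf onto every edge of every partial tree.
enumerate_edge_matrices <- function(n) {
  base <- cbind(rep(n + 1L, 3L), 1:3)
  if (n == 3L) return(list(base))
  trees <- list(base)
  for (l in 4:n) {
    z <- n + l - 2L
    nxt <- vector("list", length(trees) * (2L * (l - 1L) - 3L))
    j <- 0L
    for (em in trees) {
      for (k in seq_len(nrow(em))) {
        j <- j + 1L
        nxt[[j]] <- rbind(em[-k, , drop = FALSE],
                          c(em[k, 1L], z), c(z, em[k, 2L]), c(z, l))
      }
    }
    trees <- nxt
  }
  trees
}

edge_matrix_to_tree <- function(em, labels) {
  n <- length(labels)
  ntot <- 2L * n - 2L
  adj <- vector("list", ntot)
  for (k in seq_len(nrow(em))) {
    u <- em[k, 1L]; v <- em[k, 2L]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  new_rfs_tree(adj, c(labels, rep(NA_character_, ntot - n)), validate = FALSE)
}

#' Enumerate all unrooted binary tree topologies on a label set
#'
#' Generates each topology exactly once by deterministic stepwise leaf
#' insertion; there are (2n-5)!! of them, which bounds the usable range to
#' 3--9 leaves.
#'
#' @param labels character vector of 3 to 9 distinct leaf labels
#' @return list of binary `rfs_tree` objects
#' @export
enumerate_binary_trees <- function(labels) {
  labels <- sort(unique(as.character(labels)))
  n <- length(labels)
  if (n < 3L || n > 9L) {
    stop("enumeration supported for 3 to 9 leaves ((2n-5)!! growth); got ", n)
  }
  lapply(enumerate_edge_matrices(n), edge_matrix_to_tree, labels = labels)
}

# Non-trivial split bitmasks of a tree given as an edge matrix on nodes
# 1..ntot with leaves 1..nleaf (leaf i = bit 2^(i-1)). Canonical form: bit 1
# set. Peels leaves inward, accumulating side masks.
edge_matrix_masks <- function(em, nleaf, pc) {
  ntot <- max(em)
  ne <- nrow(em)
  deg <- tabulate(c(em[, 1L], em[, 2L]), ntot)
  inc <- vector("list", ntot)
  for (k in seq_len(ne)) {
    inc[[em[k, 1L]]] <- c(inc[[em[k, 1L]]], k)
    inc[[em[k, 2L]]] <- c(inc[[em[k, 2L]]], k)
  }
  mask <- c(2L^(seq_len(nleaf) - 1L), rep(0L, ntot - nleaf))
  edone <- rep(FALSE, ne)
  emask <- integer(ne)
  queue <- which(deg == 1L)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    k <- inc[[v]][!edone[inc[[v]]]]
    if (length(k) != 1L) next   # last remaining hub
    edone[k] <- TRUE
    u <- if (em[k, 1L] == v) em[k, 2L] else em[k, 1L]
    emask[k] <- mask[v]
    mask[u] <- mask[u] + mask[v]
    deg[u] <- deg[u] - 1L
    if (deg[u] == 1L) queue <- c(queue, u)
  }
  full <- 2L^nleaf - 1L
  m <- emask
  m <- ifelse(m %% 2L == 1L, m, full - m)
  m <- m[pc[m + 1L] >= 2L & pc[m + 1L] <= nleaf - 2L]
  unique(m)
}

popcount_table <- function(nbits) {
  pc <- integer(2L^nbits)
  for (m in seq_len(2L^nbits - 1L)) pc[m + 1L] <- pc[m %/% 2L + 1L] + m %% 2L
  pc
}

# table mapping a bitmask over the full label space to the corresponding
# bitmask over the sub-space of `sub_idx` (indices into the full bit order)
restriction_table <- function(nbits, sub_idx) {
  bitval <- integer(nbits)
  bitval[sub_idx] <- 2L^(seq_along(sub_idx) - 1L)
  tab <- integer(2L^nbits)
  for (m in seq_len(2L^nbits - 1L)) {
    low <- m - bitwAnd(m, m - 1L)              # lowest set bit
    b <- as.integer(log2(low)) + 1L
    tab[m + 1L] <- tab[m - low + 1L] + bitval[b]
  }
  tab
}

tree_split_masks <- function(t, labels, pc) {
  sp <- bipartitions(t, nontrivial_only = TRUE)
  vapply(sp, function(s) {
    m <- sum(2^(match(s$side_a, labels) - 1L))
    if (m %% 2 == 1) m else 2^length(labels) - 1 - m
  }, 0, USE.NAMES = FALSE)
}

#' Exhaustive Robinson-Foulds supertree search
#'
#' Enumerates every unrooted binary topology on the union of the profile's
#' leaf sets, scores each against all source trees, and returns the exact
#' optimum. Also verifies on every call that the trees minimizing the total
#' RF distance are exactly the trees maximizing the total split support.
#'
#' @param profile list of `rfs_tree` source trees whose label union has at
#'   most 9 leaves
#' @return list with `min_rf`, `max_sf`, `n_opt` (number of optimal
#'   topologies) and `argmin` (list of optimal `rfs_tree`s)
#' @export
brute_force_supertree <- function(profile) {
  stopifnot(is.list(profile), length(profile) >= 1L)
  s <- sort(unique(unlist(lapply(profile, tree_labels))))
  n <- length(s)
  if (n < 3L || n > 9L) stop("exhaustive search supported for 3 to 9 leaves; got ", n)
  pc <- popcount_table(n)
  ems <- enumerate_edge_matrices(n)

  src <- lapply(profile, function(ti) {
    si <- tree_labels(ti)
    idx <- match(si, s)
    ni <- length(si)
    pci <- popcount_table(ni)
    masks <- if (ni >= 4L) tree_split_masks(ti, si, pci) else integer(0)
    list(ni = ni, tab = restriction_table(n, idx), pci = pci,
         masks = masks, fulli = 2L^ni - 1L)
  })

  rf <- numeric(length(ems))
  sf <- numeric(length(ems))
  for (j in seq_along(ems)) {
    tm <- edge_matrix_masks(ems[[j]], n, pc)
    rfj <- 0L
    sfj <- 0L
    for (ss in src) {
      if (ss$ni < 3L) {
        sfj <- sfj + ss$ni
        next
      }
      r <- ss$tab[tm + 1L]
      r <- r[r != 0L & r != ss$fulli]
      r <- ifelse(r %% 2L == 1L, r, ss$fulli - r)
      r <- r[ss$pci[r + 1L] >= 2L & ss$pci[r + 1L] <= ss$ni - 2L]
      r <- unique(r)
      shared <- sum(r %in% ss$masks)
      rfj <- rfj + (length(r) - shared) + (length(ss$masks) - shared)
      sfj <- sfj + shared + ss$ni
    }
    rf[j] <- rfj
    sf[j] <- sfj
  }
  opt <- which(rf == min(rf))
  opt_sf <- which(sf == max(sf))
  stopifnot(identical(opt, opt_sf))  # RF-minimal binary trees = SF-maximal
  labels <- s
  list(min_rf = as.integer(min(rf)),
       max_sf = as.integer(max(sf)),
       n_opt = length(opt),
       argmin = lapply(ems[opt], edge_matrix_to_tree, labels = labels))
}

#' Exhaustive maximum-weight independent set
#'
#' Enumerates every subset of the vertex set (bitmask enumeration, at most
#' 20 vertices) and returns the maximum total weight of an independent one.
#' Serves as the optimality oracle for the min-cut solver.
#'
#' @param g an `rfs_incompat_graph`
#' @return maximum independent-set weight (numeric)
#' @export
brute_force_mwis <- function(g) {
  nv <- nrow(g$vertices)
  if (nv > 20L) stop("exhaustive MWIS limited to 20 vertices; got ", nv)
  if (nv == 0L) return(0)
  adjmask <- numeric(nv)
  if (nrow(g$edges)) {
    for (k in seq_len(nrow(g$edges))) {
      a <- g$edges[k, 1L]; b <- g$edges[k, 2L]
      adjmask[a] <- adjmask[a] + 2^(b - 1L)
      adjmask[b] <- adjmask[b] + 2^(a - 1L)
    }
  }
  subsets <- 0:(2^nv - 1)
  ok <- rep(TRUE, length(subsets))
  wt <- numeric(length(subsets))
  for (v in seq_len(nv)) {
    inset <- bitwAnd(subsets, 2^(v - 1L)) != 0
    ok <- ok & !(inset & bitwAnd(subsets, adjmask[v]) != 0)
    wt <- wt + g$vertices$weight[v] * inset
  }
  max(wt[ok])
}
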