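# Robinson-Foulds distance, split support, and profile scoring.
#
# All pairwise scores are computed on the shared leaf set after homeomorphic
# restriction, counting trivial as well as non-trivial bipartitions (every
# pendant edge contributes one shared split). Degenerate convention: with
# fewer than three shared leaves both restrictions are stars, so RF = 0 and
# SF = |X|; an empty shared leaf set is an error.

shared_leaves <- function(t1, t2) intersect(tree_labels(t1), tree_labels(t2))

#' Robinson-Foulds distance between two trees
#'
#' The size of the symmetric difference of the two bipartition sets, taken
#' after restricting both trees to their shared leaf set X. Returns 0 when
#' |X| < 3 (both restrictions are stars).
#'
#' @param t1,t2 `rfs_tree` objects with a non-empty shared leaf set
#' @return non-negative integer
#' @export
rf_distance <- function(t1, t2) {
  x <- shared_leaves(t1, t2)
  if (!length(x)) stop("trees share no leaves")
  if (length(x) < 3L) return(0L)
  c1 <- names(bipartitions(restrict_tree(t1, x)))
  c2 <- names(bipartitions(restrict_tree(t2, x)))
  length(setdiff(c1, c2)) + length(setdiff(c2, c1))
}

#' Split support between two trees
#'
#' The number of shared bipartitions (trivial ones included) after
#' restriction to the shared leaf set X. Returns |X| when |X| < 3.
#'
#' @inheritParams rf_distance
#' @return non-negative integer
#' @export
sf_support <- function(t1, t2) {
  x <- shared_leaves(t1, t2)
  if (!length(x)) stop("trees share no leaves")
  if (length(x) < 3L) return(length(x))
  c1 <- names(bipartitions(restrict_tree(t1, x)))
  c2 <- names(bipartitions(restrict_tree(t2, x)))
  length(intersect(c1, c2))
}

#' Score a supertree against a profile of source trees
#'
#' For each source tree the Robinson-Foulds distance, the split support, and
#' the false-negative count (source bipartitions missing from the restricted
#' supertree) are reported, together with their totals. The supertree must
#' contain every source-tree leaf.
#'
#' @param t an `rfs_tree`, the supertree
#' @param a a list of `rfs_tree` source trees (a profile)
#' @return an object of class `rfs_score_report`: list with `per_tree`
#'   (data.frame with columns tree, rf, sf, fn) and totals `rf_total`,
#'   `sf_total`, `fn_total`
#' @export
profile_scores <- function(t, a) {
  stopifnot(is.list(a), length(a) >= 1L)
  labs <- tree_labels(t)
  per <- data.frame(tree = seq_along(a), rf = 0L, sf = 0L, fn = 0L)
  for (i in seq_along(a)) {
    si <- tree_labels(a[[i]])
    missing <- setdiff(si, labs)
    if (length(missing)) {
      stop("supertree is missing source-tree leaf: ", missing[1L])
    }
    ci <- names(bipartitions(a[[i]]))
    if (length(si) < 3L) {
      per$rf[i] <- 0L
      per$sf[i] <- length(si)
      per$fn[i] <- 0L
      next
    }
    cts <- names(bipartitions(restrict_tree(t, si)))
    per$rf[i] <- length(setdiff(cts, ci)) + length(setdiff(ci, cts))
    per$sf[i] <- length(intersect(cts, ci))
    per$fn[i] <- length(setdiff(ci, cts))
  }
  structure(list(per_tree = per,
                 rf_total = sum(per$rf),
                 sf_total = sum(per$sf),
                 fn_total = sum(per$fn)),
            class = "rfs_score_report")
}

#' @export
print.rfs_score_report <- function(x, ...) {
  cat("supertree score report\n")
  print(x$per_tree, row.names = FALSE)
  cat(sprintf("totals: RF = %d, SF = %d, FN = %d\n",
              x$rf_total, x$sf_total, x$fn_total))
  invisible(x)
}
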