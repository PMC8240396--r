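# Bipartitions (splits) of a leaf set, in canonical form.
#
# Canonical form: the side containing the lexicographically smallest label
# of the universe is side_a; both sides sorted. The key "a1,a2|b1,b2" is
# what all set operations on bipartitions compare. Labels therefore must not
# contain ',' or '|' (neither survives Newick parsing anyway).

#' Construct a bipartition in canonical form
#'
#' @param a,b disjoint, non-empty character vectors whose union is the
#'   universe of the bipartition
#' @return an `rfs_split` with fields `side_a`, `side_b`, `universe`, `key`
#' @export
make_split <- function(a, b) {
  a <- sort(unique(as.character(a)))
  b <- sort(unique(as.character(b)))
  if (!length(a) || !length(b)) stop("both sides of a bipartition must be non-empty")
  if (length(intersect(a, b))) stop("bipartition sides must be disjoint")
  if (any(grepl("[,|]", c(a, b)))) stop("labels may not contain ',' or '|'")
  universe <- sort(c(a, b))
  if (universe[1L] %in% b) { tmp <- a; a <- b; b <- tmp }
  structure(list(side_a = a, side_b = b, universe = universe,
                 key = paste0(paste(a, collapse = ","), "|",
                              paste(b, collapse = ","))),
            class = "rfs_split")
}

#' Recover a bipartition from its canonical key
#' @param key a key produced by [make_split()]
#' @return an `rfs_split`
#' @export
split_from_key <- function(key) {
  sides <- strsplit(key, "|", fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop("malformed split key: ", key)
  make_split(strsplit(sides[1L], ",", fixed = TRUE)[[1]],
             strsplit(sides[2L], ",", fixed = TRUE)[[1]])
}

#' Is a bipartition trivial?
#'
#' A bipartition is trivial when one side is a single leaf.
#'
#' @param s an `rfs_split` or a canonical key
#' @return logical
#' @export
is_trivial_split <- function(s) {
  if (is.character(s)) s <- split_from_key(s)
  min(length(s$side_a), length(s$side_b)) == 1L
}

#' @export
print.rfs_split <- function(x, ...) {
  cat("[", paste(x$side_a, collapse = " "), "|",
      paste(x$side_b, collapse = " "), "]\n")
  invisible(x)
}

#' Pairwise compatibility of two bipartitions
#'
#' Two bipartitions of the same universe are compatible iff some tree
#' contains both, which holds exactly when at least one of the four pairwise
#' side intersections is empty.
#'
#' @param p1,p2 `rfs_split` objects (or canonical keys) on the same universe
#' @return logical
#' @export
are_compatible <- function(p1, p2) {
  if (is.character(p1)) p1 <- split_from_key(p1)
  if (is.character(p2)) p2 <- split_from_key(p2)
  if (!identical(p1$universe, p2$universe)) {
    stop("bipartitions have different universes")
  }
  sides_compatible(p1$side_a, p1$side_b, p2$side_a, p2$side_b)
}

# compatibility on raw label vectors; no universe validation
sides_compatible <- function(a1, b1, a2, b2) {
  !length(intersect(a1, a2)) || !length(intersect(a1, b2)) ||
    !length(intersect(b1, a2)) || !length(intersect(b1, b2))
}

#' Restrict a bipartition to a label subset
#'
#' @param s an `rfs_split`
#' @param r character vector of labels
#' @return an `rfs_split` on universe `intersect(universe, r)`, or `NULL`
#'   when either restricted side is empty
#' @export
restrict_split <- function(s, r) {
  a <- intersect(s$side_a, r)
  b <- intersect(s$side_b, r)
  if (!length(a) || !length(b)) return(NULL)
  make_split(a, b)
}
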