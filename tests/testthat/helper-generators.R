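# Shared generators for the test suite. Everything is seeded; fixtures are
# rebuilt in code at test time.

# a seeded overlapping source-tree pair on a small label union, suitable for
# exhaustive cross-checks
small_pair <- function(seed, n_model = 7L, spr_max = 2L) {
  labs <- letters[seq_len(n_model)]
  model <- random_binary_tree(labs, seed = seed)
  withr::with_seed(seed + 10000L, {
    ov <- sort(sample(labs, sample(4:min(6L, n_model), 1L)))
    spr <- sample(0:spr_max, 1L)
  })
  k <- min(2L, (n_model - length(ov)) %/% 2L)
  overlapping_pair(model, ov, extra_per_side = k,
                   disagreement_spr = spr, seed = seed + 20000L)
}

# a mid-size pair with guaranteed extra subtrees, for invariant suites
invariant_pair <- function(seed, n_model = 12L, n_overlap = 6L) {
  labs <- paste0("t", sprintf("%02d", seq_len(n_model)))
  model <- random_binary_tree(labs, seed = seed)
  withr::with_seed(seed + 30000L, {
    ov <- sort(sample(labs, n_overlap))
    spr <- sample(0:2, 1L)
  })
  overlapping_pair(model, ov, extra_per_side = 3L,
                   disagreement_spr = spr, seed = seed + 40000L)
}

# a random weighted bipartite graph in the incompatibility-graph container
random_bipartite_graph <- function(seed, max_v = 16L) {
  withr::with_seed(seed, {
    nv <- sample(2:max_v, 1L)
    n1 <- sample(seq_len(nv - 1L), 1L)
    src <- rep(1:2, c(n1, nv - n1))
    w <- sample(1:6, nv, replace = TRUE)
    edges <- matrix(integer(0), ncol = 2)
    for (a in which(src == 1L)) {
      for (b in which(src == 2L)) {
        if (stats::runif(1) < 0.3) edges <- rbind(edges, c(a, b))
      }
    }
    structure(list(vertices = data.frame(key = paste0("k", seq_len(nv)),
                                         source = src, weight = w,
                                         stringsAsFactors = FALSE),
                   edges = edges),
              class = "rfs_incompat_graph")
  })
}

# every compatible subset of a set of split keys (bitmask enumeration)
all_compatible_subsets <- function(keys) {
  keys <- unique(keys)
  m <- length(keys)
  stopifnot(m <= 16L)
  splits <- lapply(keys, split_from_key)
  comp <- matrix(TRUE, m, m)
  if (m >= 2L) {
    for (i in 1:(m - 1L)) {
      for (j in (i + 1L):m) {
        comp[i, j] <- comp[j, i] <- are_compatible(splits[[i]], splits[[j]])
      }
    }
  }
  out <- list()
  for (mask in 0:(2^m - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) != 0)
    good <- TRUE
    if (length(members) >= 2L) {
      for (i in members) {
        if (!all(comp[i, members])) { good <- FALSE; break }
      }
    }
    if (good) out[[length(out) + 1L]] <- keys[members]
  }
  out
}

# independent restriction oracle: restrict every split of t whose sides both
# meet r (bypasses restrict_tree entirely)
restricted_split_keys_oracle <- function(t, r) {
  keys <- character(0)
  for (s in bipartitions(t)) {
    rs <- restrict_split(s, r)
    if (!is.null(rs) ) keys <- c(keys, rs$key)
  }
  unique(keys)
}
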