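# Tree container, Newick round-trips, restriction, and pairwise scores.

test_that("Newick parsing unroots, discards lengths, and rejects bad input", {
  t <- parse_newick("(A,((B,x),((C,y),(D,E))));")
  expect_s3_class(t, "rfs_tree")
  expect_identical(tree_labels(t), sort(c("A", "B", "C", "D", "E", "x", "y")))
  expect_true(is_binary_tree(t))
  expect_length(bipartitions(t), 11L)               # 2n-3 edges for n = 7
  expect_length(bipartitions(t, nontrivial_only = TRUE), 4L)

  # branch lengths and internal labels are parsed then dropped
  t2 <- parse_newick("((a:1.5,b:0.2)inner:3,(c:1,d:1));")
  expect_true(trees_isomorphic(t2, parse_newick("((a,b),(c,d));")))

  expect_error(parse_newick("((a,b),(a,c));"), "duplicate")
  expect_error(parse_newick("((a,b),(c,d"), "malformed")
  expect_error(parse_newick("(a,b))(;"), "malformed")
})

test_that("three-leaf star is the unique topology and writes canonically", {
  s <- parse_newick("(c,a,b);")
  expect_identical(write_newick(s), "(a,b,c);")
  expect_length(bipartitions(s, nontrivial_only = TRUE), 0L)
  expect_length(bipartitions(s), 3L)
})

test_that("serialization is canonical and round-trips to isomorphic trees", {
  for (seed in 1:15) {
    t <- random_binary_tree(letters[1:8], seed = seed)
    r <- parse_newick(write_newick(t))
    expect_true(trees_isomorphic(t, r))
    expect_identical(write_newick(r), write_newick(t))
  }
  # deterministic output regardless of input rotation
  a <- parse_newick("((a,b),(c,d));")
  b <- parse_newick("((d,c),(b,a));")
  expect_identical(write_newick(a), write_newick(b))
})

test_that("restriction gives the homeomorphic subtree", {
  t <- parse_newick("((a,b),((c,d),(e,f)));")
  r <- restrict_tree(t, c("a", "c", "e", "f"))
  expect_identical(tree_labels(r), c("a", "c", "e", "f"))
  expect_identical(names(bipartitions(r, nontrivial_only = TRUE)), "a,c|e,f")

  expect_true(trees_isomorphic(restrict_tree(t, tree_labels(t)), t))
  expect_length(bipartitions(restrict_tree(t, c("a", "c", "e")),
                             nontrivial_only = TRUE), 0L)
  expect_error(restrict_tree(t, character(0)), "empty")
  expect_error(restrict_tree(t, c("a", "zz")), "zz")
})

test_that("restriction agrees with the split-restriction oracle", {
  for (seed in 1:20) {
    t <- random_binary_tree(paste0("L", 1:9), seed = seed)
    r <- withr::with_seed(seed, sort(sample(tree_labels(t), sample(2:7, 1))))
    got <- names(bipartitions(restrict_tree(t, r)))
    expect_setequal(got, restricted_split_keys_oracle(t, r))
  }
})

test_that("restriction composes: restricting twice equals restricting once", {
  for (seed in 1:10) {
    t <- random_binary_tree(letters[1:9], seed = seed)
    r1 <- withr::with_seed(seed, sort(sample(letters[1:9], 7)))
    r2 <- withr::with_seed(seed + 1L, sort(sample(r1, 4)))
    expect_true(trees_isomorphic(restrict_tree(restrict_tree(t, r1), r2),
                                 restrict_tree(t, r2)))
  }
})

test_that("RF distance and split support behave on quartets", {
  q1 <- parse_newick("((a,b),(c,d));")
  q2 <- parse_newick("((a,c),(b,d));")
  expect_identical(rf_distance(q1, q1), 0L)
  expect_equal(rf_distance(q1, q2), 2)
  expect_equal(sf_support(q1, q2), 4)    # only the four trivial splits
  expect_equal(sf_support(q1, q1), 5)    # all 2n-3 splits of a binary tree
})

test_that("RF is a metric on the enumerated 5-leaf topologies", {
  trees <- enumerate_binary_trees(letters[1:5])
  n <- length(trees)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) d[i, j] <- rf_distance(trees[[i]], trees[[j]])
  }
  expect_true(all(d == t(d)))
  expect_true(all(diag(d) == 0L))
  expect_true(all(d[upper.tri(d)] > 0L))  # enumeration has no duplicates
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(d[i, j], d[i, k] + d[k, j])
  }
})

test_that("scores across unequal leaf sets restrict to the shared set", {
  t1 <- parse_newick("((a,b),((c,d),(e,f)));")
  t2 <- parse_newick("((a,b),(c,(d,g)));")     # shares a,b,c,d
  expect_identical(rf_distance(t1, t2),
                   rf_distance(restrict_tree(t1, c("a", "b", "c", "d")),
                               restrict_tree(t2, c("a", "b", "c", "d"))))
  # fewer than three shared leaves: degenerate star convention
  t3 <- parse_newick("((a,b),(y,z));")
  expect_identical(rf_distance(t1, t3), 0L)
  expect_equal(sf_support(t1, t3), 2)
  expect_error(rf_distance(t1, parse_newick("((p,q),(r,s));")), "share no leaves")
})

test_that("profile scores satisfy the binary-restriction identity", {
  # rf_i + 2 sf_i = 2|S_i| - 3 + |C(T_i)| for binary supertrees
  for (seed in 1:10) {
    pr <- small_pair(seed)
    s <- union(tree_labels(pr$t1), tree_labels(pr$t2))
    t <- random_binary_tree(s, seed = seed + 99L)
    rep <- profile_scores(t, pr)
    for (i in 1:2) {
      si <- length(tree_labels(pr[[i]]))
      ci <- length(bipartitions(pr[[i]]))
      expect_identical(rep$per_tree$rf[i] + 2L * rep$per_tree$sf[i],
                       2L * si - 3L + ci)
    }
    expect_identical(rep$rf_total, sum(rep$per_tree$rf))
  }
})

test_that("split support plus false negatives is constant over supertrees", {
  # sf_total + fn_total = sum_i |C(T_i)| for any supertree, binary or not
  for (seed in 1:10) {
    pr <- invariant_pair(seed)
    total_c <- length(bipartitions(pr$t1)) + length(bipartitions(pr$t2))
    ctx <- rfs_context(pr$t1, pr$t2)
    multi <- build_initial_tree(ctx)              # heavily multifurcating
    bin <- exact_rfs_2(pr$t1, pr$t2, seed = seed)$tree
    for (t in list(multi, bin)) {
      rep <- profile_scores(t, pr)
      expect_identical(rep$sf_total + rep$fn_total, total_c)
    }
  }
})

test_that("profile scoring errors name a missing leaf", {
  t <- parse_newick("((a,b),(c,d));")
  src <- parse_newick("((a,b),(c,q));")
  expect_error(profile_scores(t, list(src)), "q")
  expect_identical(profile_scores(t, list(t, t))$rf_total, 0L)
})

test_that("split compatibility matches the four-intersection criterion", {
  u <- letters[1:5]
  p1 <- make_split(c("a", "b"), c("c", "d", "e"))
  p2 <- make_split(c("a", "b", "c"), c("d", "e"))
  expect_true(are_compatible(p1, p1))
  expect_true(are_compatible(p1, p2))
  q1 <- make_split(c("a", "b"), c("c", "d"))
  q2 <- make_split(c("a", "c"), c("b", "d"))
  expect_false(are_compatible(q1, q2))
  # compatible pairs coexist in an actual tree; incompatible pairs in none
  trees <- enumerate_binary_trees(letters[1:4])
  holds <- vapply(trees, function(t) {
    keys <- names(bipartitions(t))
    all(c(q1$key, q2$key) %in% keys)
  }, TRUE)
  expect_false(any(holds))
  expect_error(are_compatible(p1, q1), "universe")
})

test_that("bipartition canonical form is idempotent and validates", {
  s <- make_split(c("d", "c"), c("a", "b"))
  expect_identical(s$side_a, c("a", "b"))
  expect_identical(split_from_key(s$key)$key, s$key)
  expect_true(is_trivial_split(make_split("a", c("b", "c"))))
  expect_false(is_trivial_split(s))
  expect_error(make_split(c("a"), c("a", "b")), "disjoint")
  expect_error(make_split(character(0), "a"), "non-empty")
})
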