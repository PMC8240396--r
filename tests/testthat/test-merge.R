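# The refinement pipeline: initial tree, trivial-split placement, single
# refinements, binary resolution, and the full exact merge.

test_that("initial tree maximizes p2 and restricts to contractions", {
  for (seed in 1:8) {
    pr <- invariant_pair(seed)
    ctx <- rfs_context(pr$t1, pr$t2)
    ti <- build_initial_tree(ctx)
    expect_setequal(tree_labels(ti),
                    union(tree_labels(pr$t1), tree_labels(pr$t2)))
    expect_identical(p_scores(ctx, ti)$p2, length(split_pi(ctx)$pi2))
    # restriction to X carries only trivial splits (hub star)
    expect_length(bipartitions(restrict_tree(ti, ctx$x),
                               nontrivial_only = TRUE), 0L)
    # every bipartition of the restriction to S_i occurs in T_i (contraction)
    for (i in 1:2) {
      src <- if (i == 1L) pr$t1 else pr$t2
      keys <- names(bipartitions(restrict_tree(ti, tree_labels(src))))
      expect_true(all(keys %in% names(bipartitions(src))))
    }
  }
  # no extras: the initial tree is the star on X
  t <- random_binary_tree(letters[1:5], seed = 1)
  ctx <- rfs_context(t, t)
  expect_length(bipartitions(build_initial_tree(ctx), nontrivial_only = TRUE),
                0L)
})

test_that("trivial-split placement reaches p1 = w*(Triv) without moving p2", {
  for (seed in 1:8) {
    pr <- invariant_pair(seed)
    ctx <- rfs_context(pr$t1, pr$t2)
    st <- rfs2:::rfs_init_state(ctx)
    before <- p_scores(ctx, st$tree)
    st <- add_trivial_bipartitions(st)
    after <- p_scores(ctx, rfs2:::canonical_tree(st$tree))
    expect_identical(after$p1, w_star(ctx, ctx$triv))
    expect_identical(after$p2, before$p2)
  }
  # no extras anywhere: placement is a no-op
  t <- random_binary_tree(letters[1:5], seed = 2)
  ctx <- rfs_context(t, t)
  st <- rfs2:::rfs_init_state(ctx)
  st2 <- add_trivial_bipartitions(st)
  expect_true(trees_isomorphic(st$tree, st2$tree))
})

test_that("each refinement gains exactly w* and satisfies the restriction identity", {
  for (seed in 1:8) {
    pr <- invariant_pair(seed)
    ctx <- rfs_context(pr$t1, pr$t2)
    st <- add_trivial_bipartitions(rfs2:::rfs_init_state(ctx))
    g <- build_graph(ctx)
    i_set <- selected_splits(g, max_weight_independent_set(g))
    p_prev <- p_scores(ctx, rfs2:::canonical_tree(st$tree))
    for (key in sort(intersect(i_set, ctx$nontriv))) {
      prev_tree <- rfs2:::canonical_tree(st$tree)
      st <- refine_with_bipartition(st, key)
      check_state_invariants(st)
      cur_tree <- rfs2:::canonical_tree(st$tree)
      p_cur <- p_scores(ctx, cur_tree)
      expect_identical(p_cur$p1 - p_prev$p1, w_star(ctx, key))
      expect_identical(p_cur$p2, p_prev$p2)
      # C(T'|_{S_i}) grows by exactly the source splits restricting to key;
      # when key is absent from backbone i, the new edge contributes one
      # extra non-source bipartition (which cannot affect p1)
      backbones <- list(ctx$c1x, ctx$c2x)
      for (i in 1:2) {
        src <- if (i == 1L) pr$t1 else pr$t2
        si <- tree_labels(src)
        old <- names(bipartitions(restrict_tree(prev_tree, si)))
        new <- names(bipartitions(restrict_tree(cur_tree, si)))
        gained <- names(Filter(function(s) {
          rs <- restrict_split(s, ctx$x)
          !is.null(rs) && rs$key == key
        }, bipartitions(src)))
        expect_true(all(union(old, gained) %in% new))
        surplus <- setdiff(new, union(old, gained))
        if (key %in% backbones[[i]]) {
          expect_length(surplus, 0L)
        } else {
          expect_length(surplus, 1L)
          rs <- restrict_split(split_from_key(surplus), ctx$x)
          expect_identical(rs$key, key)
          expect_false(surplus %in% names(bipartitions(src)))
        }
      }
      p_prev <- p_cur
    }
  }
})

test_that("refinement rejects applied, incompatible, and unknown splits", {
  # find a seeded fixture whose backbones genuinely conflict
  exercised <- FALSE
  for (seed in 1:20) {
    pr <- invariant_pair(seed)
    ctx <- rfs_context(pr$t1, pr$t2)
    st <- add_trivial_bipartitions(rfs2:::rfs_init_state(ctx))
    g <- build_graph(ctx)
    i_set <- sort(intersect(selected_splits(g, max_weight_independent_set(g)),
                            ctx$nontriv))
    if (!length(i_set)) next
    applied <- NULL
    conflicting <- NULL
    for (key in i_set) {
      inc <- Filter(function(k) {
        !are_compatible(split_from_key(k), split_from_key(key))
      }, ctx$nontriv)
      if (length(inc)) {
        applied <- key
        conflicting <- inc[[1L]]
        break
      }
    }
    if (is.null(applied)) next
    st2 <- refine_with_bipartition(st, applied)
    expect_error(refine_with_bipartition(st2, applied), "already present")
    expect_error(refine_with_bipartition(st2, conflicting), "incompatible")
    absent <- make_split(ctx$x[c(1, 3)], ctx$x[-c(1, 3)])
    if (!(absent$key %in% names(st$sv))) {
      expect_error(refine_with_bipartition(st, absent, validate = FALSE),
                   "pending")
    }
    exercised <- TRUE
    break
  }
  expect_true(exercised)
})

test_that("binary resolution refines deterministically, never losing support", {
  b <- random_binary_tree(letters[1:7], seed = 4)
  expect_true(trees_isomorphic(resolve_to_binary(b, seed = 1), b))
  star4 <- parse_newick("(a,b,c,d);")
  r1 <- resolve_to_binary(star4, seed = 1)
  expect_true(is_binary_tree(r1))
  expect_true(trees_isomorphic(r1, resolve_to_binary(star4, seed = 1)))
  for (seed in 1:6) {
    pr <- invariant_pair(seed)
    multi <- exact_rfs_2(pr$t1, pr$t2, relax = TRUE)$tree
    res <- resolve_to_binary(multi, seed = seed)
    expect_true(is_binary_tree(res))
    expect_true(all(names(bipartitions(multi)) %in% names(bipartitions(res))))
    expect_gte(profile_scores(res, pr)$sf_total,
               profile_scores(multi, pr)$sf_total)
  }
})

test_that("merging a tree with itself returns it with zero distance", {
  for (seed in 1:5) {
    t <- random_binary_tree(letters[1:8], seed = seed)
    res <- exact_rfs_2(t, t, seed = seed)
    expect_true(trees_isomorphic(res$tree, t))
    expect_identical(res$report$rf_total, 0L)
  }
})

test_that("the worked instance is solved at total distance two", {
  ti <- toy_instance()
  expect_identical(profile_scores(ti$supertree, list(ti$t1, ti$t2))$rf_total, 2L)
  res <- exact_rfs_2(ti$t1, ti$t2, seed = 1, check_invariants = TRUE)
  expect_identical(res$report$rf_total, 2L)
  expect_setequal(tree_labels(res$tree),
                  c("A", "B", "C", "D", "E", "x", "y", "z"))
})

test_that("compatible pairs merge at distance zero", {
  for (seed in 1:6) {
    model <- random_binary_tree(paste0("m", 1:10), seed = seed)
    ov <- withr::with_seed(seed, sort(sample(tree_labels(model), 5)))
    pr <- overlapping_pair(model, ov, extra_per_side = 2,
                           disagreement_spr = 0, seed = seed)
    res <- exact_rfs_2(pr$t1, pr$t2, seed = seed)
    expect_identical(res$report$rf_total, 0L)
  }
})

test_that("relaxed output is optimal before resolution and refines to the optimum", {
  for (seed in 1:5) {
    pr <- small_pair(seed)
    rel <- exact_rfs_2(pr$t1, pr$t2, seed = seed, relax = TRUE)
    bin <- exact_rfs_2(pr$t1, pr$t2, seed = seed)
    expect_true(all(names(bipartitions(rel$tree)) %in%
                      names(bipartitions(bin$tree))))
    # the relaxed tree already attains the maximal split support
    expect_identical(rel$report$sf_total, bin$report$sf_total)
  }
})

test_that("binary-input validation names the offending vertex", {
  star <- parse_newick("(a,b,c,d);")
  q <- parse_newick("((a,b),(c,d));")
  expect_error(exact_rfs_2(star, q), "internal vertex .* degree 4")
  expect_error(exact_rfs_2(q, star), "second source tree")
})

test_that("degenerate overlaps still produce valid optimal supertrees", {
  t1 <- parse_newick("((a,b),(c,x));")
  t2 <- parse_newick("((x,p),(q,r));")       # single shared leaf x
  res <- exact_rfs_2(t1, t2, seed = 1)
  expect_true(is_binary_tree(res$tree))
  expect_setequal(tree_labels(res$tree), c("a", "b", "c", "p", "q", "r", "x"))
  expect_identical(res$report$rf_total, 0L)

  t3 <- parse_newick("((a,b),(x,y));")
  t4 <- parse_newick("((x,y),(p,q));")       # two shared leaves
  res2 <- exact_rfs_2(t3, t4, seed = 1)
  expect_true(is_binary_tree(res2$tree))
  expect_setequal(tree_labels(res2$tree), c("a", "b", "p", "q", "x", "y"))
  expect_identical(res2$report$rf_total, 0L)

  # three shared leaves: no non-trivial backbone splits, still optimal
  t5 <- parse_newick("((a,b),(c,p));")
  t6 <- parse_newick("((a,q),(b,c));")
  res3 <- exact_rfs_2(t5, t6, seed = 1)
  expect_true(is_binary_tree(res3$tree))
  expect_identical(res3$report$rf_total, 0L)

  expect_error(exact_rfs_2(parse_newick("((a,b),(c,d));"),
                           parse_newick("((p,q),(r,s));")), "share no leaves")
})

test_that("refinement order does not change the attained scores", {
  for (seed in 1:10) {
    pr <- invariant_pair(seed)
    ctx <- rfs_context(pr$t1, pr$t2)
    g <- build_graph(ctx)
    nt <- sort(intersect(selected_splits(g, max_weight_independent_set(g)),
                         ctx$nontriv))
    if (length(nt) < 2L) next
    run <- function(order) {
      st <- add_trivial_bipartitions(rfs2:::rfs_init_state(ctx))
      for (key in order) st <- refine_with_bipartition(st, key)
      p_scores(ctx, rfs2:::canonical_tree(st$tree))
    }
    base <- run(nt)
    expect_identical(run(rev(nt)), base)
    perm <- withr::with_seed(seed, sample(nt))
    expect_identical(run(perm), base)
  }
})
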