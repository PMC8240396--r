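# rfs2: exact Robinson-Foulds supertrees of two binary trees

Supertree methods combine phylogenetic trees on overlapping taxon sets into
one tree on their union, and are the glue step of divide-and-conquer
phylogeny estimation: split the taxa into overlapping subsets, infer a tree
per subset, merge. The classical merge criterion is the **Robinson-Foulds
supertree (RFS)**: over all binary trees *T* on the union *S*, minimize

    RF(T, {T1, T2}) = Σᵢ RF(T, Tᵢ),

where RF compares bipartition (split) sets after restricting both trees to
their shared leaves. Minimizing RF over binary supertrees is equivalent to
maximizing the **split support** SF(T, Tᵢ) = |C(T|_{Sᵢ}) ∩ C(Tᵢ)|, because
RF(T,Tᵢ) + 2·SF(T,Tᵢ) is a constant for binary *T*. The problem is NP-hard
for three or more input trees, but for **two binary trees** it is solvable
exactly in polynomial time — and that exact two-tree merge is what this
package implements, together with the scaffolding to use and verify it.

## The algorithm

Let `X = S₁ ∩ S₂` be the shared leaves. Each source tree `Tᵢ` decomposes
around `X` into a *backbone* `Tᵢ|_X` plus rooted *extra subtrees*; each
backbone edge `e` stands for a path `P(e)` in `Tᵢ` with weight
`w(e) = |P(e)|`. The merge then:

1. builds an initial supertree whose hub is adjacent to every shared leaf
   and every extra-subtree root — this already realizes every source split
   with a side disjoint from `X` (the `p₂` part of the split support);
2. moves the extra subtrees behind each trivial split of `X` onto the
   matching pendant path, realizing `w*(Triv)` of the `p₁` part, where
   `w*(π)` sums the weights of the edges inducing `π` in the backbones;
3. forms the bipartite **weighted incompatibility graph** of the two
   backbones (one vertex per split occurrence, weight `w(eᵢ(π))`, edges
   between incompatible splits), extracts a **maximum-weight independent
   set** exactly via max-flow/min-cut, and inserts each selected
   non-trivial split by splitting one supertree vertex — each insertion
   raises `p₁` by exactly `w*(π)`;
4. resolves the remaining multifurcations arbitrarily (seeded).

The result provably attains the maximum split support, hence the minimum
RFS score, over all binary trees on `S`.

## Worked example

```r
library(rfs2)

ti <- toy_instance()          # two sources sharing 5 of 8 leaves
res <- exact_rfs_2(ti$t1, ti$t2, seed = 1)
write_newick(res$tree)
#> [1] "(A,(((B,x),(D,E)),z),(C,y));"
res$report
#> supertree score report
#>  tree rf sf fn
#>     1  2 10  1
#>     2  0  9  0
#> totals: RF = 2, SF = 19, FN = 1
```

The merged supertree sits at Robinson-Foulds distance 2 from the first
source and 0 from the second; total 2 is optimal, which
`brute_force_supertree(list(ti$t1, ti$t2))` confirms by scoring all 10,395
binary topologies on the 8-label union. The report's SF and FN columns are
the split support and the false-negative count (source splits missing from
the restricted supertree); SF + FN is constant over supertrees, so
minimizing false negatives is the same problem as maximizing support.

Beyond the merge itself the package provides:

- `rfs_context()`, `compute_backbone()`, `build_graph()`,
  `max_weight_independent_set()` — the decomposition and selection
  machinery, exposed for inspection;
- `brute_force_supertree()`, `brute_force_mwis()`,
  `enumerate_binary_trees()` — independent exhaustive oracles;
- `decompose_by_edge()`, `short_quartets()`, `dactal_merge()` — a
  single-level divide-and-conquer pipeline with pluggable subset-tree
  estimators;
- `random_binary_tree()`, `overlapping_pair()` — seeded generators of
  model trees and overlapping source pairs with controlled disagreement;
- a command-line tool (`exec/rfs2`) with subcommands `merge`, `score`,
  `oracle`, `dactal`, `fixtures`, `dump-decomposition`, `dump-graph`.

```sh
exec/rfs2 fixtures --preset toy --out /tmp/toy
exec/rfs2 merge /tmp/toy/t1.nwk /tmp/toy/t2.nwk --out /tmp/super.nwk --report /tmp/report.tsv
```

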