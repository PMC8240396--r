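---
title: "Exact Robinson-Foulds supertrees of two trees: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact Robinson-Foulds supertrees of two trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfs2)
```

## The problem

Given two unrooted binary trees $T_1, T_2$ with leaf sets $S_1, S_2$ and
shared leaves $X = S_1 \cap S_2$, the Robinson-Foulds supertree problem
asks for a binary tree $T$ on $S = S_1 \cup S_2$ minimizing
$\mathrm{RF}(T,T_1) + \mathrm{RF}(T,T_2)$, where the RF distance between
trees with unequal leaf sets is computed after restricting both to their
shared leaves. Every edge $e$ of a tree induces a bipartition (split)
$\pi_e = [A|B]$ of its leaf set, and a tree is determined by its split set
$C(T)$; RF is the symmetric difference of split sets and the split support
$\mathrm{SF}(T,T_i) = |C(T|_{S_i}) \cap C(T_i)|$ is their intersection
size. For binary $T$,
$\mathrm{RF}(T,T_i) + 2\,\mathrm{SF}(T,T_i) = 2|S_i| - 3 + |C(T_i)|$ is
constant, so minimizing total RF and maximizing total SF are the same
optimization; similarly $\mathrm{SF} + \mathrm{FN}$ is constant for any
supertree, where FN counts source splits missing from the restriction.
These two identities are asserted over seeded fixtures in the test suite,
for binary and multifurcating supertrees respectively.

With three or more source trees the problem is NP-hard; this package
implements only the exact two-tree algorithm and treats the multi-tree
case as out of scope.

## The algorithm as implemented

**Decomposition.** Restricting $T_i$ to $X$ (minimal spanning subtree,
degree-2 vertices suppressed) gives the backbone $T_i|_X$. Every backbone
edge $e$ corresponds to a path $P(e)$ in $T_i$; its weight $w(e) = |P(e)|$
counts the path's edges. Components of $T_i$ minus the spanning subtree
are rooted *extra subtrees*; each attaches at an internal vertex of
exactly one path (the set $\mathcal{TR}(e)$, kept in path order), or — for
multifurcating sources only — directly at a backbone vertex. For a subset
$Q \subseteq X$, $\mathcal{BP}_i(Q)$ collects the backbone splits with a
side strictly inside $Q$, and $\mathcal{TRS}_i(Q)$ the extra subtrees
behind them; these drive the reattachment rules during refinement.

**Score decomposition.** Source splits whose both sides meet $X$ form
$\Pi_1$; the rest ($\Pi_2$) live inside or just above extra subtrees. The
split support of any supertree splits into $p_1 + p_2$ accordingly. The
initial supertree — a hub adjacent to every $x \in X$ and every extra
subtree root — already attains the ceiling $p_2 = |\Pi_2|$, because every
$\Pi_2$ split survives inside an intact extra subtree. The $p_1$ part is
bounded by $w^*(F)$ for the compatible split set $F$ realized on $X$,
where $w^*(\pi)$ is 0 / $w(e_1)$ / $w(e_2)$ / $w(e_1)+w(e_2)$ according to
which backbones contain $\pi$.

**Selection.** The two backbones' split occurrences form a weighted
incompatibility graph: one vertex per occurrence (a split in both
backbones contributes two vertices, each with its own weight
$w(e_i(\pi))$), edges between incompatible splits. Splits of a common
tree are mutually compatible, so the graph is bipartite by source, and
the maximum-weight independent set is found exactly by the standard
min-cut reduction (source-side capacities = weights, incompatibility arcs
uncuttable); the selected set maximizes $w^*$ over all compatible subsets
of backbone splits. `igraph::max_flow` supplies the flow primitive; the
reduction, cover extraction, and the independent brute-force oracle used
to cross-check it are implemented here.

**Refinement.** Trivial splits of $X$ are realized first by moving the
extra subtrees behind each pendant path onto that pendant edge, nearest
the leaf first, which brings $p_1$ to $w^*(\mathrm{Triv})$. Each selected
non-trivial split $\pi = [A|B]$ is then inserted by splitting the unique
vertex $v$ separating $A$ from $B$: neighbours leading to $A$ go to one
copy, neighbours leading to $B$ to the other, extra subtrees behind $\pi$
are subdivided onto the new edge in path order, extras in
$\mathcal{TRS}(A)$ / $\mathcal{TRS}(B)$ stay on their side, and each
insertion raises $p_1$ by exactly $w^*(\pi)$. Bookkeeping maps `sv` (split
$\to$ vertex to split) and `H` (vertex $\to$ pending splits) are updated
in place; `check_state_invariants()` re-derives their defining properties
from scratch and is run after every step in the invariant test suite. The
final multifurcation resolution is an arbitrary seeded refinement, which
can only add splits and therefore never lowers the attained support.

## Parameters and conventions

- `seed` (everywhere): the algorithm's optimum is deterministic; seeds
  only steer arbitrary choices (final resolution, generator draws). All
  randomness flows through `withr::with_seed`, so any call is reproducible
  from its arguments.
- `relax = TRUE` in `exact_rfs_2()` returns the pre-resolution tree,
  which is optimal for the relaxed (not-necessarily-binary) split-fit
  problem. Note the relaxed RF and SF problems are *not* equivalent: on
  the `single_edge_profile(n)` construction the star minimizes relaxed RF
  at $n-3$ while the caterpillar maximizes SF at $(n-3)(n+1)$, and the
  acceptance tests pin all four closed forms.
- Degenerate overlaps: pairwise scores with $|X| < 3$ are defined as
  RF $= 0$, SF $= |X|$ (both restrictions are stars); an empty overlap is
  an error. For $|X| \le 3$ no non-trivial backbone split exists, the
  graph phase is skipped, and any binary supertree consistent with the
  trivial structure is optimal; $|X| \in \{1, 2\}$ is handled by direct
  construction through the same trivial-path machinery. These conventions
  are ours — the degenerate regime is not pinned down by the theory — and
  they are documented rather than erroring because divide-and-conquer
  callers do produce thin overlaps.
- Canonical forms: bipartitions store the side containing the smallest
  label first, sorted; Newick output is rooted at the internal vertex
  adjacent to the smallest leaf with children ordered by smallest
  descendant label. All set operations compare canonical keys, and
  repeated runs emit identical bytes. Label comparisons are exact;
  labels may not contain `,` or `|`.
- Tie-breaks: the selected independent set is deterministic because
  vertices enter the flow network in canonical order; among equal-weight
  optima any choice yields the same score, and the order-invariance tests
  permute the insertion order of the selected splits and verify identical
  $(p_1, p_2)$.
- Unconstrained extra subtrees during a refinement (those in neither
  $\mathcal{TRS}(A)$ nor $\mathcal{TRS}(B)$ nor behind $\pi$) attach to
  the $A$-side copy, deterministically; either side preserves the
  invariants. When the two sources both contribute extras to the new
  edge, source-1 extras precede source-2 extras; only the within-source
  path order matters for the score, so the interleaving is a free choice
  fixed for determinism.
- Vertex-attached extra subtrees (attachment at a backbone vertex rather
  than inside a path) cannot occur for binary sources — a source vertex
  kept in the spanning subtree with three backbone directions has no free
  edge — so they are represented for multifurcating inputs but belong to
  no $\mathcal{TR}(e)$ and hence to no $\mathcal{TRS}$ set.

## The divide-and-conquer layer

`decompose_by_edge()` splits a guide tree's taxa by an internal edge
$[A|B]$ into $A \cup P$ and $B \cup P$, where $P$ holds the $p$
topologically nearest leaves to the edge from each of the four incident
subtrees, ties included. The default edge is a most-balanced internal
edge; the theory needs only *some* edge, so the choice is a parameter.
"Nearest" is edge-count distance (branch lengths are discarded at parse
time throughout). If every short quartet of the true tree — one closest
leaf per subtree around each internal edge, ties included — lies inside
one subset, the true tree is the unique compatibility supertree of its two
restrictions and the merge returns it exactly; the tests verify this
conditional over seeded 10–20-leaf models with exact-restriction
estimators, checking the coverage predicate independently. Only one
decomposition level is implemented: recursion adds nothing to the
correctness argument, and estimators are pluggable callables (file-based
in the CLI), not bundled inference methods.

## What the generators emulate — and what they do not

`overlapping_pair()` models the setting the merge is designed for: two
binary trees derived from one model tree, sharing exactly the leaf set
`overlap`, each with its own private leaves, with topological disagreement
injected by `disagreement_spr` subtree-prune-regraft moves applied to the
second tree's backbone. Moves are restricted to the backbone so the
disagreement is guaranteed to affect the supertree optimum rather than
vanishing inside private subtrees; with zero moves the pair is compatible
and the optimum is exactly 0, which the tests assert. The second tree's
private leaves are attached at random backbone positions rather than
inherited from the model, which is irrelevant to compatibility but means
the generator does not emulate *correlated* estimation error: real subset
trees disagree through estimation noise on shared signal, not independent
SPR moves. Passing tests therefore certify the combinatorial optimality
machinery, not accuracy on real data. Sequence-level simulation and
actual tree estimators are out of scope by design.

## Problem sizes in the shipped suites

Exhaustive cross-checks run where enumeration is feasible: 200 seeded
pairs with unions of at most 7 leaves (at most 945 topologies each)
against the brute-force optimum, the 8-label worked instance against all
10,395 topologies, 500 random bipartite graphs of up to 16 vertices
against bitmask-enumeration MWIS, and the $w^*$-dominance claim against
every compatible subset for overlaps of up to 6 leaves. Invariant and
order-invariance suites use 100 and 50 seeded 11-leaf fixtures with
6-leaf overlaps; the pipeline-recovery suite uses 100 models of 10–20
leaves. These sizes are chosen so each suite exercises every code path
with an independent oracle while the whole test run stays inside a couple
of minutes.

## Known limitations

- The exact guarantee covers exactly two binary source trees; the CLI and
  scoring accept multifurcating trees and larger profiles, but only for
  scoring and decomposition, never for exact optimization.
- The implementation favours clarity over asymptotics: restrictions and
  split sets are recomputed where the complexity argument would maintain
  them incrementally. The polynomial shape is preserved, but very large
  inputs would warrant the incremental bookkeeping.
- Weighted (branch-length) RF, rooted semantics, and quartet distances
  are explicitly out of scope.
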