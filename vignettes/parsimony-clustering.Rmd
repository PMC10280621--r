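---
title: "Parsimonious cladograms and single-linkage dendrograms"
author: "parsclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimonious cladograms and single-linkage dendrograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parsclust)
```

## The model

The input is a set $S$ of $m$ aligned sequences of common length $n$ over
a finite alphabet $\mathcal{A}$ (nucleotides, binary presence/absence
traits, or any categorical characters). Characters are treated as
unordered, multistate and reversible, and the distance between two
sequences is the Hamming distance $d_H$ — the number of differing sites.
Gap and ambiguity symbols are ordinary states: they count as mismatches
against every other state, since the model has no missing-data semantics.

A *cladogram* is a rooted tree whose leaves are in bijection with $S$ and
whose every node carries a sequence of length $n$ (internal nodes may
carry hypothetical sequences outside $S$). Its *parsimony length* is
$w(T) = \sum_{(x,y) \in E(T)} d_H(x, y)$. Two classical problems frame
everything here: *small parsimony* (optimally label the internal nodes of
a fixed topology — polynomial, solved by Fitch-style dynamic programming)
and *large parsimony* (minimize over topologies too — NP-complete).

## From spanning trees to cladograms

Let $G(S)$ be the complete graph on $S$ with Hamming edge weights and $T_1$
a minimum spanning tree of it. Because $d_H$ satisfies the triangle
inequality, an Euler-tour argument gives the classical 2-approximation
$w(T_1) \le 2\,w(T^*)$, hence the sandwich
$\tfrac12 w(T_1) \le w(T^*) \le w(T_1)$ around the optimum $w(T^*)$.

`mst_to_cladogram()` converts $T_1$ into a rooted cladogram of *equal*
weight. The spanning tree is oriented away from its root and peeled
inward: every current leaf $u$ contributes the edge
$(u, \mathrm{parent}(u))$ with its original weight, and the first time a
vertex serves as a parent it receives a zero-weight pendant edge to its
own leaf copy. Every element of $S$ therefore ends up as a leaf, internal
labels all lie in $S$, the pendants add nothing, and
$w(T_2) = w(T_1)$ holds as an exact integer identity (it is asserted
property-style in the test suite). Vertices of degree above two yield
multifurcations; we deliberately do not binarize, since the parsimony
length of a tree does not require binary topology. The construction does
not re-optimize labels; `fitch_label()` can be applied afterwards when a
better labeling of the same shape is wanted, but it is a separate call so
the weight-preservation contract stays testable.

Two conventions make the output reproducible where the mathematics leaves
freedom:

- **MST tie-breaking.** Multiple MSTs usually exist (the DNA quartet used
  throughout the examples has three equally light first picks). Kruskal's
  greedy scan runs over edges sorted by (weight, lexicographic id pair)
  under C collation, which fixes one canonical MST.
- **Orientation.** The peeling needs a direction; the spanning tree's
  root is the lexicographically smallest vertex id.

## Single linkage, with and without labels

`single_linkage()` is the textbook agglomeration: repeatedly merge the
two clusters at minimal single-linkage distance
$d_{BC}(C_i, C_j) = \min_{x \in C_i, y \in C_j} d_H(x, y)$. Heights are
non-decreasing (single linkage is reducible), and cutting the dendrogram
at height $t$ yields exactly the connected components of the MST after
deleting edges heavier than $t$ — a classical equivalence the test suite
checks on every simulated set. Heights are kept in raw distance units;
`normalize_heights()` divides by $n$ for the usual 0–1 scale.

`labeled_single_linkage()` additionally turns the merge tree into a
cladogram whose labels all lie in $S$: when $\hat C_i$ and $\hat C_j$
merge, the member pair $(\hat P_i, \hat P_j)$ realizing their
single-linkage minimum labels the two participating cluster nodes (a
singleton keeps its own point). This labeling is a heuristic — the tests
assert it is never better than the Fitch optimum of the same shape, and
usually it is worse.

Two more conventions:

- **Merge tie-breaking.** Equal cluster distances are resolved on the
  lexicographically smallest pair of cluster representatives (a cluster's
  representative is its smallest member id), and equal member pairs on
  the sorted id pair.
- **Root label.** The agglomeration labels the two clusters *entering*
  each merge but never the final merged cluster, so the root would stay
  unlabeled. We let the root inherit the label of its larger child (ties
  broken toward the smaller member id of the last minimum pair), and
  record the choice in the provenance table. This is an interpretation,
  not a statement of the algorithm; inheriting a child's label makes the
  edge to that child cost zero, so it never inflates the tree's weight,
  which other in-set choices could.

## Why the two trees can disagree: the demarcation instances

`make_demarcation_instance(chain_length, n)` builds binary sets of the
form chain-plus-outlier: prefix-of-ones sequences descending in steps of
one (ones counts $L, L-1, \dots, 2, 0$) plus the all-ones outlier at
distance $n$ from the all-zeros end. For $(3, 7)$ this is
$\{1111111, 1110000, 1100000, 0000000\}$ with MST weight 7. Single
linkage, being locally greedy, attaches the outlier last, and one can
show that *no* assignment of internal labels to that tree shape reaches
the MST weight: the exact minimum, computed independently by per-site
dynamic programming and by exhaustive enumeration, is 8. The site-wise
lower bound (each polymorphic site needs at least one change) equals $n$
on these sets, certifying the MST weight as the unconstrained optimum —
so the gap is attributable to the tree *shape*, not the labeling. The
test suite sweeps several $(L, n)$ configurations and checks the strict
gap on each.

## Small parsimony on multifurcating trees

`fitch_min_weight()` and `fitch_label()` implement uniform-cost dynamic
programming per site: for each node and state, the minimal cost of the
subtree given that state, combining children via
$\min(c_{\text{child}}(s), 1 + \min_{s'} c_{\text{child}}(s'))$. On
binary nodes this reduces to the classical Fitch set rule; on
multifurcations it remains exact, which matters because the MST-derived
cladograms are multifurcating whenever an MST vertex has degree above
two. Sites decompose exactly under Hamming distance, so the total is the
sum of per-site minima.

The traceback resolving one optimal labeling is deterministic: the root
takes the lexicographically smallest optimal state per site; every other
node keeps its parent's state whenever that is optimal, otherwise the
smallest optimal state. Which optimal labeling is returned is a
convention; the weight is not.

## Oracles

Everything above is verified against brute force at desk scale:

- `most_parsimonious_tree()` enumerates all $(2m-3)!!$ rooted binary
  leaf-labeled topologies by stepwise insertion and scores each by the
  small-parsimony DP. Binary enumeration suffices for the optimum:
  any multifurcating tree is a binary tree with zero-length edges, and
  contracting edges never lowers the weight below the best binary
  resolution. The default refusal bound is 8 leaves (10,395 topologies at
  7 leaves already take seconds).
- `exhaustive_min_labeling()` enumerates every per-site assignment of
  states to internal nodes — no DP involved — and must agree with
  `fitch_min_weight()` wherever both run; this is the independent check
  of the DP.
- `parsimony_lower_bound()` is the site-wise bound
  $\sum_{\text{sites}} (\#\text{distinct states} - 1)$, used to certify
  optima.

## The simulator and what it does (not) show

`simulate_tree_sequences()` draws a rooted binary topology by uniform
stepwise leaf addition, a root sequence uniform over the alphabet, and
mutates each site independently along every edge with probability
`p_sub` (default 0.1), moving to a uniformly chosen different state. The
generating tree is returned fully labeled, giving a free upper bound on
the optimum. Defaults (6 leaves, 10 sites, 4-letter alphabet) are chosen
so that a single instance is verifiable by the oracles in well under a
second; the property suites vary 3–8 leaves, 6–15 sites, binary to
4-letter alphabets, and substitution probabilities 0–0.4, with fixed
seeds so failures replay exactly. The bound-checking suite runs 100
simulated sets at 4–7 leaves (sizes weighted toward the cheap end so the
whole run stays within a couple of minutes of CPU).

The simulator emulates independent-site substitution on a tree — the
regime in which parsimony is a sensible criterion. It does not model
indels, rate heterogeneity, back-mutation biases, recombination, or
alignment error; passing tests therefore certify the *algorithms* and
their contracts, not the adequacy of parsimony for any particular real
dataset. Real alignments (the package reads any equal-length FASTA) can
be analyzed with the same functions, but at realistic sizes only the
MST and linkage constructions apply — the oracles refuse, by design.

## Numerical and degenerate-input choices

- All Hamming arithmetic is exact integer arithmetic; normalized heights
  are the only derived floating-point quantities and are computed on
  demand, never stored, so tie-breaking never sees float drift.
- Single-sequence inputs produce degenerate but valid objects (a one-leaf
  cladogram with no edges, weight 0); clustering requires $m \ge 2$.
- Sequences are upper-cased on read; comparisons are case-insensitive.
- The F-score defaults to the pair-counting F1
  $2\,TP / (p_A + p_B)$ over co-clustered pairs, defined as 1 when both
  partitions are all singletons (they are then identical). It is
  symmetric, relabel-invariant, and 1 exactly on equal partitions. A
  cluster-matching variant (size-weighted best-match F1, averaged over
  both directions) is available via `fscore(..., variant = "matching")`;
  the two can differ, and published F-score tables rarely state which
  convention they use, so comparisons across papers should fix the
  variant explicitly.
- `cut_by_count()` on cladograms removes edges in decreasing weight
  order until the leaves fall into exactly `k` components. Removing a
  fixed `k - 1` edges can strand leafless components behind zero-weight
  pendants, which is why the removal continues until the requested count
  is reached; a depth-based alternative (`method = "depth"`) cuts all
  edges crossing a root-distance level instead.

## Known limitations

- Only single linkage is implemented; complete/average/Ward linkages
  would need their own update rules and are out of scope.
- Only unordered, reversible, uniform-cost characters: no Wagner, Dollo
  or Camin-Sokal variants, and no substitution-model distances.
- The oracles are exponential by nature and guarded accordingly; they
  exist to certify correctness, not to analyze data.
- Tree-search heuristics (NNI and the like) and Neighbor Joining are
  intentionally absent: mature libraries already provide them, and the
  point of this package is the MST and linkage constructions plus their
  exact verification.
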