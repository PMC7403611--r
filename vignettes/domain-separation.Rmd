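---
title: "Measuring archaea–bacteria separation in gene-family trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring archaea–bacteria separation in gene-family trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domainsep)
```

## The question and the two statistics

A protein family already present in the last universal common ancestor
(LUCA) should, in the absence of later interdomain gene transfer, produce
a gene tree in which archaea and bacteria form two clean clades joined by
a single branch — and because the two lineages have diverged for billions
of years, that branch should be long relative to the diversity within
each domain. `domainsep` measures both aspects of this signature on any
rooted newick tree whose leaves are assigned to two groups, conventionally
`A` (archaea) and `B` (bacteria).

**The split count `s`.** We define `s` as the minimum number of edges
whose removal leaves no connected component containing both an A leaf and
a B leaf. On a tree this is exactly the parsimony score of the two-state
leaf character: every most-parsimonious assignment of states to internal
nodes has `s` state-change edges, and those edges form a minimal
separating set. `s = 1` is reciprocal monophyly; each extra split is most
naturally read as (at least) one transfer or unresolved paralogy event.
`s` is purely topological — branch lengths and the position of the root
do not affect it — and `s = 0` only for the degenerate case of a
single-domain tree, which the batch layer excludes from analysis.

**The distance ratios.** With `n` archaeal and `m` bacterial leaves and
`d(x, y)` the patristic distance (sum of branch lengths along the unique
path), the mean ordered-pair distances within and between domains give

$$\bar{D} = \frac{1}{2}\,\frac{\bar d_{AA} + \bar d_{BB}}{\bar d_{AB}},
\qquad D = \frac{\min(\bar d_{AA}, \bar d_{BB})}{\bar d_{AB}},$$

(also written Dav and Dmin; `D ≤ D̄` always, a minimum never exceeding a
mean). Both are dimensionless and invariant under rescaling all branch
lengths, so trees inferred under different rate calibrations are
comparable. Values near 1 mean the domain labels carry no distance
signal; values near 0 mean a long interdomain stem. On the worked quartet
`((a1:1,a2:1):1,(b1:1,b2:1):1)` the means are
`d̄AA = d̄BB = 2, d̄AB = 4`, so `D̄ = D = 0.5`; stretching the stem
(`((a1:0.1,a2:0.1):5,(b1:0.1,b2:0.1):5)`) drives `D̄` down to
`0.2/10.2 ≈ 0.0196`.

```{r quartet}
q <- read_newick("((a1:1,a2:1):1,(b1:1,b2:1):1);")
m <- domain_map(list(A = "^a", B = "^b"), tree = q)
domain_distances(q, m)
```

## Algorithms and numerical choices

**Split counting.** `count_splits()` runs a two-state Sankoff-style
dynamic program: a postorder pass accumulates, for each node and each
state, the minimal number of change edges in the subtree, and the score
is the minimum at the root. On binary trees this is the classic Fitch
count. On multifurcations we deliberately do *not* use the naive
union/intersection generalization of Fitch, because it undercounts: a
four-way polytomy with two A children and two B children needs two
changes, not one. The per-state DP is exact on arbitrary node degrees, so
polytomies are handled natively rather than being randomly resolved —
random resolution would make `s` depend on an RNG seed, which we consider
unacceptable for a descriptive statistic.

**Locating splits and reading support.** Among the (often many)
most-parsimonious reconstructions we report one, chosen deterministically:
the root state is the cheaper one (ties broken toward domain A), and the
preorder traceback keeps the parent's state whenever the child's two
options tie (the DELTRAN convention, which pushes changes leafward). Each
change edge's child node is the lca of a separated same-domain subtree;
the support value annotating that split is read at the *parent* node `p`
of the lca, matching how internal-node labels describe the bipartition
below them in standard newick output. When `p` is an unannotated root the
split contributes `NA`, and the per-tree mean support is the mean over the
defined values only. Because the traceback depends on the root position,
the *located* edges can differ between rootings of the same tree even
though `s` itself cannot; users comparing support values across trees
should root consistently (e.g. all trees midpoint- or outgroup-rooted).

**Support scales.** Bootstrap pipelines emit supports on 0–100, Bayesian
and approximate-likelihood tools on 0–1. Supports are passed through
verbatim; `normalize = TRUE` divides by 100 only when every defined
support exceeds 1, so evidence is never silently rescaled.

**Distances.** `mean_pairwise_distances()` avoids the O(n²) pairwise sum:
an edge of length ℓ separating (n₁ᴬ, n₁ᴮ) leaves below from (n₂ᴬ, n₂ᴮ)
above lies on n₁ᴬ·n₂ᴬ of the A–A paths, n₁ᴮ·n₂ᴮ of the B–B paths and
n₁ᴬ·n₂ᴮ + n₁ᴮ·n₂ᴬ of the A–B paths, so one postorder pass over the edges
yields all three sums. The test suite verifies agreement with explicit
path-walking and with `ape`'s cophenetic matrix to a relative tolerance
of 1e-9 on trees up to 200 leaves.

**Degenerate inputs.** The ordered-pair denominator `n(n−1)` vanishes for
a single-leaf domain, so `d̄AA` is undefined for `n < 2` and the ratios
propagate as `NA` with an explanatory flag — substituting 0 would
fabricate a statistic. Similarly `d̄AB = 0` (an all-zero-length tree)
yields flagged `NA` ratios rather than an infinity: such a tree carries
no distance signal. Missing or negative branch lengths are hard errors
that name the offending edge. Unmapped leaves abort a batch run by
default (`on_unmapped = "prune"` and `"exclude"` are explicit opt-ins),
because silently dropping leaves biases both `s` and `D̄`.

## The permutation null model

To know whether an observed `(s, D̄)` pair is remarkable, the package
keeps each tree's topology and branch lengths fixed and shuffles the
domain labels at controlled proportions — by default 30%, 50% and 90% A,
spanning the compositions typical of real family collections. Shuffling
uses exact counts (`k = round(p·L)` A leaves, clamped to `[1, L−1]` so
both groups always exist) rather than i.i.d. labeling, reproducing the
stated proportions exactly on every tree. Each replicate's RNG stream is
derived from `(master seed, tree id, proportion, replicate index)` via a
32-bit FNV-1a hash, so results are identical whatever the execution
order, and a rerun with the same configuration is byte-identical. The
default of 100 replicates per tree and proportion is a deliberate,
documented choice — enough to place an observed value against the null
bulk; studies of extreme tail quantiles should raise it.

On the balanced quartet the null is small enough to enumerate: of the
C(4,2) = 6 balanced labelings, 2 respect the cherries (`s = 1`) and 4
interleave them (`s = 2`), so P(s = 1) = 1/3. The test suite checks the
Monte-Carlo frequencies against this exhaustive reference. For real-sized
trees the relevant qualitative result is directional: shuffled labels
almost never produce both a single split and a low `D̄`, so observed
families in that corner are not explained by composition alone.

```{r null}
nd <- null_distribution(q, proportions = 0.5, replicates = 300, seed = 1)
summarize_null(nd, size_classes = numeric(0))
```

## The synthetic generator and what it does (not) show

`simulate_tree()` builds test fixtures with provable ground truth: two
independent random subtrees (topology from `ape::rtree()`, i.i.d.
exponential edge lengths with mean `within_rate`, default 0.1
substitutions/site — a typical within-domain branch scale for conserved
proteins) joined by a stem of `stem_length`, followed by `n_transfers`
guarded cross-domain regrafts. Guarded placement moves each transferred B
leaf onto the pendant edge of a distinct A leaf. The guarantee
`s = 1 + n_transfers` then has a short proof: any separating edge set
must spend one edge inside each transferred cherry (else its A and B
members stay connected), and one more on the path between the untouched
A leaves and the main B clade, which traverses no cherry pendant; the
planted cut achieves exactly that bound. Feasibility requires
`n_transfers ≤ min(n_A, n_B) − 1`: with every A leaf hosting a transfer,
cutting all `n_A` A-pendants would be cheaper than the planted cut and
the ground truth would be wrong. An unguarded placement mode is
deliberately absent: a fixture whose truth is only probably correct is
not a fixture.

For transfer-free simulations the generator also records the realized
`D̄`, computed from the realized branch lengths via `ape`'s cophenetic
path sums — an independent route from the package's edge-contribution
implementation, which keeps the truth channel and the code under test
separate.

The generator emulates the *geometry* the statistics respond to (stem
length, within-domain diversity, transfer count). It does not emulate
alignment noise, rate heterogeneity across sites or lineages,
reconstruction artifacts such as long-branch attraction, or paralog
contamination. Passing recovery tests therefore demonstrates that the
statistics measure what they claim on known-truth trees — not that tree
inference from real alignments is reliable, which is a property of the
upstream pipeline.

## Batch analysis

`run_batch()` applies validation, split counting and the distance summary
to every tree in a collection, excluding single-domain trees with a
machine-readable reason (a family must contain both domains to be
informative). The headline tally counts single-split trees with at least
`min_per_domain` leaves on each side — default 10, below which shuffled
labels produce single splits too readily for the count to mean much.
`glance()` returns the tallies, `scatter_table()` the `(s, D̄)` pairs
with an explicit count of omitted undefined rows, and `write_report()` a
deterministic TSV (fixed column order, `NA` strings, 6 significant
digits).

Problem sizes used by the automated checks — exhaustive shape
enumeration to 7 leaves, 1,000-tree oracle sweeps to 12 leaves for cuts
and 200 leaves for distances, 500 guarded recovery simulations to 64
leaves per domain, 50 replicates per stem-grid point — were chosen so the
full suite exercises every code path at sizes where the independent
brute-force oracles remain exact and fast.

## Known limitations

- `s` counts branches, not events: a single transfer of a whole clade and
  several independent single-gene transfers can give the same count.
- Support aggregation inherits the rooting dependence of "parent node"
  described above.
- The distance ratios use the branch lengths as given; no model-based
  re-estimation, ultrametric normalization or rate correction is applied.
- The null model randomizes labels only; topology- or branch-length
  randomization would answer different questions and is out of scope.
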