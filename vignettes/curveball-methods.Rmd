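---
title: "Curveball randomization of networks with fixed degrees: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curveball randomization of networks with fixed degrees: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curveballr)
```

## The problem

Null models in network ecology (and far beyond) ask whether an observed
structural pattern — nestedness, co-occurrence scores, motif counts — is
surprising given the degrees of the nodes. Answering that requires sampling
*uniformly* from the set of all simple networks with exactly the observed
degree sequence. The classic tool is the switching (rewiring) chain: pick two
edges, swap their ends, reject the move if a self-loop or duplicate edge
would arise. It converges to the uniform distribution but mixes slowly,
because each accepted step changes only two edges.

The Curveball family accelerates this by trading *sets* of edges. Picture
each node's adjacency set as a kid's stack of trading cards: at each step two
kids meet and exchange a random bundle of the cards they do not share. One
such trade can perform many switches at once, while still preserving every
degree exactly.

`curveballr` implements the three variants on a common adjacency-list core:

* **bipartite** — rows of a 0/1 biadjacency matrix trade column indices
  (species × site matrices, host–parasite webs);
* **directed** — nodes trade out-neighbours (food webs);
* **undirected** — nodes trade neighbours, with a symmetry repair step
  (co-occurrence and contact networks).

## The trade move

For a selected pair $(i, j)$ with adjacency sets $A_i$, $A_j$, the
*tradeable sets* are

$$A_{i-j} = A_i \setminus (A_j \cup \{j\}), \qquad
  A_{j-i} = A_j \setminus (A_i \cup \{i\}),$$

i.e. the elements held by one but not the other, excluding the partner node
itself so that no self-loop can ever be created (for bipartite rows the
exclusion terms are dropped — rows and columns are different node classes).
The trade then draws a uniformly random $|A_{i-j}|$-subset $S$ of the pool
$A_{i-j} \cup A_{j-i}$ and sets

$$B_i = (A_i \setminus A_{i-j}) \cup S, \qquad
  B_j = (A_j \setminus A_{j-i}) \cup ((A_{i-j} \cup A_{j-i}) \setminus S).$$

In the undirected case a repair step restores symmetry: every node traded
from $j$ to $i$ replaces $j$ by $i$ in its own set, and conversely. The
*size* of a trade is the number of elements that change owner; the draw may
re-select the status quo, giving size 0, and the chain then simply repeats
the current network.

Three properties make this a correct sampler, and all three are enforced as
tests rather than assumed:

1. **Degree preservation** — $|B_i| = |A_i|$, $|B_j| = |A_j|$ by
   construction; the suite replays $10^4$ random trades per kind and
   validates the full invariant set after each.
2. **Reversibility** — the same pair on the traded state can restore the
   original in one trade (`reverse_proposal()`); checked for $10^3$
   executed trades per kind.
3. **Switch correspondence** — every valid switch equals a size-one trade:
   at least one in the directed case, and *exactly two* in the undirected
   case (trade the switched endpoints between the owner pair, or trade the
   owners between the endpoint pair). `trades_realizing_switch()`
   enumerates these exhaustively, and the tests confirm the counts on 100
   random graphs per kind.

```{r lemma}
set.seed(1)
g <- er_gnm(10, 16, "undirected")
sw <- enumerate_switches(g)[[1]]
trades_realizing_switch(g, apply_switch(g, sw))
```

## Chains, step counting and laziness

`run_chain()` drives three variants with *identical step semantics*: each
step draws one uniformly random unordered node (row) pair — or edge pair for
the switching baseline — and every attempt counts as a step, whether it
commits a change, a size-0 trade, or a rejected switch. This makes
perturbation traces comparable across variants at equal x-coordinates.

The size-0 trades are not waste: they are the laziness that makes the
Curveball chain aperiodic. The contrast is instructive. The package also
implements the size-one-restricted baseline (a swap algorithm shaped like
the Curveball: same pair selection, but exactly one element of each
tradeable set is exchanged whenever both are non-empty). On state spaces
where *every* pair admits an exchange — for example the six 3×3 permutation
matrices — that variant swaps at literally every step and therefore
alternates permutation parity deterministically: it is periodic, and
samples taken at even spacing see only half the space. The test suite
demonstrates this and verifies that its time-average (odd spacing) is
uniform again. The full Curveball never has this defect, because the subset
draw can always re-select the status quo.

A single seed drives pair choice and subset choice through R's global RNG in
a fixed documented order, so a `(graph, seed)` pair reproduces a chain
bit-for-bit; `run_chain()` and every command-line entry point expose that
seed.

## Frozen triangles and the directed state space

Switches (and hence trades) cannot reverse an oriented triangle
$1 \to 2 \to 3 \to 1$ when nothing else in the graph offers a switch
partner: the triangle's orientation is an invariant of the chain, and part
of the realization space is unreachable. `curveballr` handles this with a
one-shot preprocessing step, `reorient_frozen_triangles()`, which flips each
*frozen* 3-cycle with probability 1/2 before the chain starts.

Deciding frozenness exactly requires care, and the package takes a
deliberately conservative route:

* `is_frozen()` implements a **local criterion**: a 3-cycle is frozen when
  its reversal would still be a simple graph and none of its three arcs
  participates in any valid switch with any arc of the graph.
* `reachability_oracle()` provides the **ground truth at desk scale**: it
  enumerates every realization of the degree sequence and partitions the
  space into switch-connectivity classes by breadth-first search. A
  triangle is truly frozen iff its reversal lands in a different class.
* The test suite asserts that the local criterion agrees with the oracle on
  every enumerable instance it touches — hand-built fixtures plus random
  5-node digraphs containing 3-cycles. The criterion is certified by this
  agreement, not by a closed-form theorem.

The oracle settles two points one might guess wrongly. First, a triangle
accompanied by *any* disjoint arc is not frozen: the cross switch is always
available, and the oracle confirms the space is a single class. Second, two
disjoint oriented triangles defrost *each other* — their arcs switch across
components, which is exactly the classical "hexagonal move" arising from
ordinary switches — so the only frozen triangles are those whose every
potential switch partner collides. Re-orientation is therefore rare on
realistic graphs, and the package leaves non-frozen triangles strictly
alone.

Because the re-orientation is a per-run preprocessing step, sampling
*with* re-orientation uses `independent_sampler()` (fresh re-orientation +
chain per retained sample) rather than one long walk; for chains that need
no re-orientation, `chain_sampler()` spaces samples along a single walk.

```{r triangle}
tri <- curveball_fixtures()$oriented_triangle
res <- run_chain(tri, 1000, "curveball", seed = 1)
res$n_zero_trades                    # every step was a size-0 trade
reorient_frozen_triangles(tri, seed = 8)
```

## Uniformity testing

`enumerate_realizations()` lists every realization of a degree sequence by
pruned recursive enumeration (0/1 matrices with fixed margins; zero diagonal
for directed; symmetric for undirected), keyed canonically by the flattened
matrix, with brute-force limits of 4×4 bipartite and 7 unimode nodes.
`uniformity_test()` then maps chain samples to realization indices and
applies Pearson's chi-square against the uniform expectation. Membership is
asserted sample by sample: a graph outside the space is reported as
contamination (a broken move), never as a statistical fluctuation.

Defaults: burn-in 1 000 steps, spacing 10 steps between retained samples,
and a pass threshold of $p > 10^{-3}$ required from a majority of 3
independent seeds. Spaced samples reduce autocorrelation; the majority rule
guards against the false rejections that any fixed $\alpha$ must eventually
produce. The standard spaces exercised are the 6 permutation matrices
(bipartite 3×3, all margins 1), the 12 labelled 5-cycles (undirected,
all degrees 2), the 9 derangement digraphs ($n = 4$, in = out = 1), and the
2 triangle orientations (directed, with re-orientation). As a negative
control, the directed chain *without* re-orientation started at the
oriented triangle must never leave its start state.

## Convergence diagnostics

`perturbation_score()` is the mixing proxy: the fraction of the original
network's edges absent from the randomized one. `convergence_experiment()`
runs the Curveball and the size-one-restricted chain from the same start on
a generated ensemble and tabulates long-format traces plus mean ± sd per
recorded step. Expectations borne out by the tests: on dense directed ER
networks ($n = 200$, $m = 10n$, 5 000 steps recorded every 100) the
Curveball's mean trace dominates the restricted chain's at every recorded
step beyond 500, while on low-out-degree preferential-attachment networks
the advantage narrows, because out-sets of size ≤ 3 rarely support trades
larger than one and shared hub targets shrink the tradeable pools further.

## Generators

* `er_gnm()` — uniform $G(n, m)$ via igraph, converted to adjacency lists.
  Ensemble parameterization: $n$ uniform on an interval, $m = d \cdot n$
  with $d$ uniform on an interval (defaults 100–1000 and 5–50; the
  experiments above use reduced sizes, stated where used).
* `ba_network()` — sequential preferential attachment started from a
  (directed) triangle; each new node draws its out-degree uniformly from
  {1, 2, 3} and attaches to distinct targets with probability proportional
  to in-degree + 1 (degree + 1 undirected). The exact construction behind
  the published power-law ensembles is not fully specified anywhere we
  could rely on, so this is a documented modeling choice engineered to
  reproduce the property that matters for the mixing comparison: all
  out-degrees in {1, 2, 3}. The +1 smoothing lets zero-in-degree nodes be
  chosen at all.
* `realize_degree_sequence()` — deterministic greedy constructions
  (Havel–Hakimi; Gale–Ryser margins with largest-residual column choice;
  Kleitman–Wang with lexicographic (in, out) residual ordering — the
  in-degree-only ordering is *not* sufficient, as the 1-regular triangle
  sequence already shows). Realizability is checked first and violations
  are reported by name (parity, Erdős–Gallai, Gale–Ryser, Fulkerson-type).
  The output is an initial state for a chain, never a random sample.

## What the synthetic ensembles do and do not show

The generators emulate the two ensemble families used in the mixing
experiments — homogeneous ER networks and heavy-tailed low-out-degree
preferential-attachment networks — plus small enumerable fixtures. They do
not emulate degree-correlated, modular, or trophically structured real
networks (a real food web is not an ER draw), so passing traces and
uniformity tests certify the *sampler* — degree preservation, reachability,
unbiasedness on enumerable spaces — not any ecological conclusion about a
particular empirical network. For empirical work the chains should simply
be run on the network itself via `cmd_randomize()`.

## Numerical and interface choices

* Node indices are 1-based contiguous integers internally; arbitrary string
  labels from edge-list files are mapped on read and restored on write.
  Undirected edges live twice in the adjacency lists but serialize once,
  endpoints in label order, lines sorted — output is byte-stable.
* Duplicate edges in input files are collapsed with a warning count;
  self-loops are rejected outright (the moves could never remove them).
* Trade proposals are immutable records; `apply_trade()` verifies the
  proposal still matches the graph (stale proposals are a consistency
  error, catching misuse in user code).
* Problem sizes used by the test suite and the acceptance script: 100
  switch/trade correspondence cases per kind on 8–12 nodes; $10^4$
  validated trades and $10^3$ inversions per kind; 60 000 (suite) or
  20 000 (script) retained samples per uniformity seed; ER ensembles of 10
  replicates at $n = 200$. These are the package's default desk-scale
  protocol; all are plain function arguments and scale up unchanged.

## Limitations

* Weighted, multi-, and temporal graphs are out of scope, as are GraphML
  and GML dialects; inputs are plain edge lists and 0/1 TSV matrices.
* `is_frozen()` is certified by oracle agreement on enumerable instances,
  not proved; on graphs far outside that regime the conservative local
  test could in principle misclassify a triangle whose switch partners are
  blocked only transiently. All certified instances agree.
* Mixing-time guidance is empirical (perturbation plateaus), not a formal
  total-variation bound; `convergence_experiment()` exists precisely to
  let users pick a step count for their own network class.
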