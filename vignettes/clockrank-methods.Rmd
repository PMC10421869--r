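---
title: "Methods: network propagation and wiring-signature prioritization of clock-associated proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network propagation and wiring-signature prioritization of clock-associated proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clockrank)
```

## The problem

Circadian clocks are built from a small set of core oscillator proteins, but
the processes they drive run through a much larger halo of clock-*associated*
proteins. When a species has a protein-interaction network (PIN) but little
functional annotation — the situation for most non-model plants — the
network's local topology around the known core-clock proteins is the main
signal available for finding that halo. clockrank implements a two-branch
prioritization scheme over an undirected PIN and a seed list of core-clock
proteins:

1. **Propagation (RWR branch).** A random walk with restart spreads
   probability mass outward from the seeds; nodes that retain mass at
   stationarity are topologically close to the clock.
2. **Wiring similarity (GDV branch).** Each node is summarized by its
   graphlet degree vector — how often it sits at each automorphism orbit of
   the 2–4-node graphlets — and nodes *wired like* a seed are retained even
   if they are far from it. This captures the observation that functional
   similarity tracks local wiring patterns, not only shared neighborhoods.

Each branch is then disciplined twice: an empirical permutation FDR strips
candidates explained by network architecture alone, and an
annotation-enrichment similarity (MAS) strips candidates without functional
support. The final call is the union of the two branches.

## The restart walk

With a column-stochastic transition operator $W$ (entry $1/\deg(j)$ for each
interaction $\{i,j\}$) and seed distribution $P_0$ (mass $1/s$ on each of $s$
seeds), the walk iterates

$$P_{i+1} = (1-r)\,W P_i + r\,P_0$$

until $\lVert P_{i+1}-P_i\rVert_1$ falls below the tolerance. Because $W$ is
stochastic on positive-degree nodes, the map is a contraction with factor
$(1-r)$: the L1 gap is bounded by $2(1-r)^i$ and convergence is geometric —
at the default $r = 0.8$ a handful of iterations suffice. `rwr_solve_direct()`
solves the same fixed point $(I-(1-r)W)P = rP_0$ densely and serves as an
exact cross-check on small graphs.

One modeling point deserves a note. Applying a *column*-normalized operator
directly to the probability vector is the standard restart-walk formulation
and is what conserves probability mass; formulations that transpose a
column-normalized adjacency do not. clockrank uses the mass-conserving form;
mass conservation at every iteration is asserted in the test suite.

Nodes with stationary probability strictly above the raw threshold
($10^{-5}$ by default) become raw candidates. Seeds are excluded from the
candidate list by default, since the object of interest is the proteins
associated with the clock rather than the clock itself; the flag
`exclude_seeds` restores them.

## Graphlet degree vectors

The nine connected non-isomorphic graphs on 2–4 nodes admit 15 automorphism
orbits; `build_catalog()` derives both counts from scratch by enumerating
graphs and their label permutations, and the package's orbit numbering
(edge = 0 … K4 = 14) follows the standard literature order. A node's
signature counts, for each orbit, the connected induced subgraphs through
the node occupying that orbit. Orbit 0 is the node degree; the handshake
identity $\sum_v \mathrm{o0}(v) = 2|E|$ and the triangle identity
$\sum_v \mathrm{o3}(v) = 3\,\#\triangle$ are asserted in the tests. Counting
is exact subset enumeration (no sampling), implemented in compiled code with
an ESU-style scheme that visits each connected subgraph exactly once; an
independent brute-force enumerator written in R validates it on random
graphs.

Similarity between two signatures $u, v$ is

$$S_{GDV}(u,v) = 1 - \frac{\sum_i |u_i - v_i|}{\sum_i (u_i + v_i)},$$

computed by default on the 11 non-redundant orbits
$\{0,1,2,4,5,6,7,8,9,10,11\}$ — the triangle orbit and the three orbits of
the densest graphlets are linear combinations of the others. A full-15 mode
is available (`use_reduced = FALSE`). Two all-zero signatures compare as 1
(identically — emptily — wired); after the degree filter this case cannot
arise. Before any signature is computed, nodes of degree below 3 are removed
in a single pass (degrees measured on the input network, no iterative
cascade): sparse peripheries of interactomes are where incompleteness
concentrates. Nodes of degree exactly 3 are kept — the operative rule is
"remove degree < 3".

The similarity threshold is not fixed a priori: starting at 0.96 the cutoff
drops in steps of 0.01 until every seed has at least one non-seed node at or
above it. The comparison at the selected grid value is inclusive ($\ge$),
so a seed whose best match sits exactly on a grid point is counted as
matched.

## Permutation nulls

Both branches get an empirical FDR $p(g) = \theta / n$ with strict
exceedance counting ("higher than"), no $+1$ correction — $p = 0$ is
therefore possible and anticonservative in the usual small-sample sense;
this follows the plain $\theta/n$ definition. Defaults use $n = 1000$
replicates at $\alpha = 0.05$ (strict $<$).

* **RWR null:** random seed sets of the same size drawn uniformly without
  replacement; $\theta$ counts null runs whose stationary probability of the
  candidate exceeds the observed one. Because observed and null runs are
  exchangeable when the observed seeds are themselves random, the p-values
  are calibrated — the acceptance suite checks this with a KS test.
* **GDV null:** degree-preserving rewired networks, each produced by
  $10 \cdot |E|$ attempted double-edge swaps (a swap is rejected if it would
  create a self-loop or duplicate edge, so the degree sequence is preserved
  *exactly*). $\theta$ counts null networks where the similarity of the
  candidate's *best-matching real-network seed pair* exceeds the observed
  similarity. The looser reading — any seed exceeding — would inflate
  $\theta$ and is not used; fixing the pair keeps the null statistic aligned
  with the statistic that nominated the candidate.

Null networks are streamed through an iterator and never stored, and orbit
signatures on each null network are computed only for the nodes involved in
the comparisons. All draws derive from one root seed through per-replicate
derived streams, so any branch replays identically in isolation.

## Enrichment similarity (MAS)

For a gene $g$ with closed neighborhood $H(g)$ ($g$ plus its interactors,
$n = |H(g)|$), a term $A$ annotating $M$ of the $N$ network proteins, and
$m$ annotated members of $H(g)$, the enrichment score is the upper-tail
hypergeometric surprisal

$$S(g,A) = -\log_{10} \sum_{k=m}^{n}
  \frac{\binom{M}{k}\binom{N-M}{n-k}}{\binom{N}{n}}.$$

$N$ counts *all* network nodes, not just annotated ones; annotations of
genes absent from the network are ignored when computing $M$. The tail is
evaluated in log space and capped at 300 when it underflows — the downstream
cosine is scale-sensitive and an unbounded spike would swamp every other
term. $m = 0$ scores exactly 0.

The profile $ES(g)$ collects $S(g,A)$ over the terms annotating at least one
member of $H(g)$ (all other terms necessarily score 0). Functional
similarity between two genes is the cosine
$\Gamma = ES(g)\cdot ES(g') / (\lVert ES(g)\rVert\,\lVert ES(g')\rVert)$,
aligned on the union of the two genes' term sets with absent terms filled
with 0; a gene with an all-zero profile has $\Gamma = 0$ with everything.
MAS is a candidate's maximum $\Gamma$ over the seed proteins, and a
candidate survives only with MAS $\ge 0.75$ in **both** the GO and the
pathway namespace. The threshold is inclusive; GO-graph semantics (ancestor
propagation, information content) are deliberately out of scope — terms are
opaque labels.

## The synthetic benchmark

`generate_benchmark()` builds the study conditions the pipeline is tested
under: a preferential-attachment backbone (800 nodes, 3 edges per new node —
scale-free and small-world like real interactomes, and dense enough that
nearly every node clears the degree-3 filter), a 30-node module whose pairs
get extra wiring with probability 0.3, 9 seeds inside the module with the
remaining 21 members as planted truth, and two annotation namespaces (30 GO
terms, 15 pathway terms; 5 "clock-like" terms each) where module nodes carry
module terms with probability 0.8 against a 0.05 background. Preferential
attachment was chosen over a configuration model because only the broad
degree shape matters for the property tests, not an exact generative match.
Seeds sit inside the planted module so that both proximity and wiring
similarity are informative — the premise of the method.

What the generator does *not* emulate: interactome noise (false-positive
edges), annotation incompleteness correlated with degree, multiple
overlapping functional modules, and the sheer size of a real PIN
(13,604 nodes in the motivating application). Passing tests on this
benchmark therefore demonstrate internal correctness and better-than-chance
recovery under favourable, known-truth conditions — not field performance on
a real interactome.

Tests and the acceptance script run the full pipeline at 200 permutations
per branch on the 800-node default; these sizes are the package's chosen
desk-scale operating point, small enough to iterate on while keeping the
empirical FDR resolution (1/200) well below $\alpha = 0.05$.

## Numerical and degenerate-input conventions

* Self-loops and duplicate (including reversed) edges are dropped at read
  time with a message; both branches assume a simple graph.
* Isolated nodes yield an all-zero transition column and a warning; walk
  mass reaching them would leak, so they are effectively outside the walk's
  support.
* Strictness conventions follow the rule's wording everywhere: raw RWR
  candidates use $>\tau$; permutation exceedance uses $>$; significance uses
  $p < \alpha$; the GDV grid value and MAS use $\ge$.
* Exceedance comparisons in the GDV null carry a $10^{-12}$ guard so exact
  ties arising from integer-ratio similarities are never counted as
  exceedances through floating-point noise.
* `filter_min_degree(net, 0)` is the identity; an all-removed network is
  returned empty rather than erroring (only a network with no *edges at
  construction* is rejected).
* The pipeline is a pure function of (inputs, config, root seed); the run
  report records every intermediate count, the selected GDV threshold, and
  the seed.

## Limitations

* Exact orbit enumeration scales with the number of connected 4-subsets;
  hub-heavy networks far beyond $10^4$ nodes would need the orbit-relation
  counting methods used by dedicated graphlet tools.
* The permutation FDR is not corrected for multiple testing beyond the
  fixed $\alpha$, matching the method it implements.
* MAS depends entirely on annotation coverage: an unannotated true positive
  cannot survive the dual-namespace filter, and on sparsely annotated
  genomes the enrichment stage is the binding constraint.
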