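---
title: "Percolation centrality: methods and design notes"
author: "percnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Percolation centrality: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(percnet)
library(igraph)
```

## The problem

Classical centrality measures are static: a node's betweenness depends
only on topology, so it cannot tell apart a network with one infected
village from the same network with a hundred.  During an unfolding
contagion -- an infection moving over a contact network, a virus over a
computer network, disease over a network of towns -- the nodes that
matter most for *further* spread are those that sit on the paths out of
the currently percolated region.  Percolation centrality makes that
precise by attaching the nodes' percolation states to the geodesics that
betweenness already counts.

Each node $v$ carries a state $x_v \in [0,1]$ at a given timestep: $0$
non-percolated, $1$ fully percolated, intermediate values partial
percolation (say, the infected fraction of a town).  A *percolated path*
is a geodesic whose source is (at least partially) percolated.

## The measures

**Betweenness** (the base measure), over ordered pairs with endpoints
excluded, normalized to $[0,1]$:
$$BC(v) = \frac{1}{(N-1)(N-2)} \sum_{s \ne v \ne r}
  \frac{\sigma_{sr}(v)}{\sigma_{sr}},$$
where $\sigma_{sr}$ counts geodesics from $s$ to $r$ and
$\sigma_{sr}(v)$ those passing through $v$ as an interior node.

**Percolation centrality** weights each pair by its source's state,
normalized by the total percolation available to $v$'s sources:
$$PC^t(v) = \frac{1}{N-2} \sum_{s \ne v \ne r}
  \frac{\sigma_{sr}(v)}{\sigma_{sr}} \cdot \frac{x_s^t}{S^t - x_v^t},
  \qquad S^t = \sum_i x_i^t.$$
Subtracting $x_v$ from $S$ makes each evaluation node's source weights a
probability distribution (every column of `weight_matrix()` sums to 1),
which pins down two exact reductions:

* *uniform states* $x_v = \alpha > 0$: every weight is $1/(N-1)$ and
  $PC = BC$ element-wise;
* *single-source averaging*: with one source at level $\alpha$ the
  weight is 1 regardless of $\alpha$ (scale invariance), and averaging
  the single-source scenarios recovers $BC$ exactly.

On the second reduction, one subtlety is worth recording.  For node $v$
the scenario in which $v$ itself is the sole source contributes nothing:
$S - x_v = 0$, there is no valid source for $v$ under the endpoint
convention, and $PC(v) = 0$ by convention.  The identity
$\mathrm{avg}_u\, PC^{(u)}(v) = BC(v)$ therefore holds exactly when the
average runs over the $N-1$ admissible origins; this is the form the
package tests to $10^{-12}$, implemented as the sum over all $N$
scenarios divided by $N-1$.

**Source--target variant.**  When only paths from more- to
less-percolated nodes are meaningful (a path between two equally
infected towns carries no potential spread), each ordered pair is
weighted by the ramp of the state difference, normalized over pairs:
$$PC_{st}(v) = \sum_{s \ne v \ne r} \frac{\sigma_{sr}(v)}{\sigma_{sr}}
  \, w_{s,r}, \qquad
  w_{s,r} = \frac{R(x_s - x_r)}{\sum_{s' \ne r'} R(x_{s'} - x_{r'})},$$
with $R(y) = \max(y, 0)$.  The normalization constant here is a design
choice the package documents prominently: raw ramp weights are scaled to
sum to one over ordered pairs and no further leading factor is applied,
so $PC_{st}(v) \in [0,1]$ reads as the weighted fraction of percolated
paths through $v$.  Under uniform states every ramp weight vanishes and
the measure is identically zero.

**Current-flow (random-walk) forms.**  Contagion rarely follows
geodesics, so each measure has an electrical analogue: treat every link
as a unit resistor, pump a unit current from $s$ to $r$, and replace the
geodesic fraction by the throughput $I_{sr}(v)$, half the summed
absolute currents on $v$'s incident edges.  `current_flow_betweenness()`
averages $I_{sr}(v)$ over pairs; the percolation variants reuse the
same source and pair weights as their shortest-path counterparts.  On
trees the electrical and geodesic measures coincide exactly (all current
follows the unique path), which the tests exploit as an oracle.

**Hop distance**, the contrasting simple measure: the smallest number of
hops from a node to any node with state $\ge \theta$ (default
$\theta = 1$), 0 for nodes already satisfying the predicate, `Inf` when
the node's component has none.

## Numerical and algorithmic choices

* PC and BC are computed by breadth-first geodesic counting with
  reverse-order dependency accumulation, $O(NM)$ total; the percolation
  weighting multiplies each source's accumulated dependency by $x_s$ and
  divides per node by $S - x_v$ afterwards, so it adds only constant
  work per source (the runtime-ratio test bounds PC at under
  $3\times$ BC empirically; measured ratios are near 1).
  The source--target variant accumulates with per-target coefficients
  $w_{s,r}$.
* Geodesic counts are accumulated in doubles; they are exact integers
  well beyond the sparse graph sizes (up to $\sim 10^4$ nodes) the
  package targets.
* Degenerate denominators are conventions, not errors: $S = 0$ gives
  all-zero PC; $S - x_v = 0$ gives $PC(v) = 0$; an all-zero ramp gives
  all-zero $PC_{st}$; graphs with $N < 3$ score zero everywhere
  (no interior triples).
* Disconnected pairs ($\sigma_{sr} = 0$) contribute nothing ($0/0 := 0$).
* The electrical solver factorizes the grounded Laplacian densely per
  connected component (intended for up to a few thousand nodes); pairs
  across components contribute zero, since the electrical problem is
  undefined there.  Conservation holds to solver precision; tests use
  $10^{-9}$.  The uniform-state reduction of current-flow PC to
  current-flow betweenness is exact on connected graphs; on disconnected
  graphs the two measures normalize differently (per-component versus
  global) by construction.
* Directed graphs are supported throughout the shortest-path measures
  (the definitions are stated for directed graphs); the electrical
  measures are undirected by nature and reject directed input.
* Ties in immunization rankings break stably by graph node order, so
  runs are exactly reproducible.

## The brute-force oracles

Every fast algorithm has an independent reference implementation:
`oracle_geodesics()` enumerates all shortest paths by backtracking over
distance layers obtained from `igraph::distances()` (not from the
package's own BFS), `oracle_percolation_centrality()` evaluates the
definitions literally on the enumerated paths, and
`oracle_current_flow()` solves the whole network with a Laplacian
pseudoinverse (`MASS::ginv`) in plain loops.  The test suite holds the
fast paths to the oracles at $10^{-10}$ (geodesic measures) and
$10^{-9}$ (electrical measures) across hundreds of random instances.
The oracles are exponential in the worst case and guarded by a
path-count cap (default $10^6$ per pair); they are test instruments,
not production code.

## The spread model

`simulate_spread()` runs discrete-time susceptible--infected dynamics:
synchronous updates, an independent Bernoulli($\beta$) exposure per edge
to each currently infected neighbour (so $k$ infected neighbours infect
with probability $1-(1-\beta)^k$; the implementation draws once per
exposed node from that law, which is the same distribution), one-step
latency before a new infectee transmits, no recovery.  The seed node is
percolated at step 1; with $\beta = 1$ infection times are exactly
$1 + $ hop distance, which the tests assert as an exact BFS equivalence.
Simulator states are binary; partial states are exercised through the
centrality APIs, matching how the measures are meant to be used during
a spread.

$\beta$ is intrinsically context-dependent (a property of the contagion,
not of the method); the package default of $0.5$ is a neutral config
default, and every experiment records the value used.

## The immunization experiment

`run_intervention()` implements the protocol: spread until $\rho\%$ of
nodes are fully percolated, rank the non-percolated nodes by a strategy
-- percolation centrality or betweenness descending, or hop distance
ascending (ring vaccination: closest to the contagion first, a
deliberate reading of "top-ranked" for a measure where smaller is more
urgent) -- immunize the top $\lfloor i\% \cdot N \rfloor$ (state
permanently zero, never transmit), and record the steps from
intervention until the fully percolated count reaches
`saturation_fraction * N` (default $0.9$, exposed as configuration).
Runs that never saturate are censored at 30 post-intervention steps and
enter cell means at 30.  Scores are computed once, at the intervention
timestep.  Replicates whose spread dies out before reaching $\rho\%$ are
redrawn with a deterministically perturbed seed, up to a bounded budget.

`experiment_grid()` sweeps $(\rho, i)$ cells for several strategies with
replicate seeds shared across cells and strategies, so comparisons are
paired; the per-cell winner is the strategy with the longest mean delay,
with exact ties recorded as ties.  The qualitative regime the
harness reproduces on scale-free networks: betweenness-based protection
of the core wins when intervention is late or resources scarce (high
$\rho/i$); ring vaccination wins when intervention is early and
resources plentiful (low $\rho/i$); percolation centrality is the
designed compromise in the critical middle ranges.

Experiments run on the dominant connected component
(`giant_component()`): across components saturation is unreachable and
the comparison degenerates to censoring everywhere.

## Synthetic networks: what they emulate and what they do not

`generate_scale_free()` draws degrees from a truncated power law
$p(k) \propto k^{-\gamma}$, $1 \le k \le k_{max}$, and realizes them
with configuration-model stub matching constrained to simple graphs
(igraph's degree-sequence samplers), so the exponent and hard cutoff
are direct inputs rather than emergent properties of a growth process.
Defaults $\gamma = 2.5$ and the natural cutoff
$k_{max} = \min(N-1, \lceil N^{1/(\gamma-1)} \rceil)$ are the package's
choices for a generic contact-like network; a degree-distribution MLE on
realized draws recovers the requested exponent to within $\pm 0.3$ at
$N = 1000$.  An `outlier_fraction` parameter is accepted and recorded
for compatibility with degree-distribution parameterizations that
designate out-lier nodes, but this generator does not interpret it.
`generate_er()` provides $G(N,M)$ and $G(N,p)$ contrasts.

These generators emulate degree heterogeneity and sparsity.  They do
not reproduce clustering, degree correlations, household/community
structure, or temporal contact patterns of real contact networks, so
passing tests demonstrate correctness of the measures and the protocol,
not epidemiological realism of any particular prediction.

Two fixed fixtures support demonstrations: `two-hub-8`, two adjacent
bridge hubs joining a left and a right triple, whose mirrored partial
state vectors make the hub nearer the heavily percolated side take the
higher PC while betweenness stays symmetric; and `alberta-like-39`, a
*synthetic* 39-node sparse contact-style network (one dominant 33-node
component, a labeled degree-1 peripheral seed) frozen as a constant.
It stands in for the kind of small outbreak contact network on which
one would track individual nodes over a simulated spread; it is not a
reproduction of any published network's topology or numbers.

## Problem sizes used by the checks

The package's own validation runs at desk scale, chosen to make the
properties sharp while keeping the whole suite quick: reductions on
hundreds of random graphs up to $N = 50$; oracle comparisons on 200
instances up to $N = 12$; spread and intervention protocol checks on the
dominant component of a 500-node scale-free draw with 20 paired
replicates per corner; generator fidelity on 50 draws at $N = 1000$;
and runtime scaling on sparse graphs up to $N = 800$.

## Known limitations

* Edge-weighted geodesics, multigraphs, and sampling/approximation
  estimators of PC are out of scope; so are recovery dynamics
  (SIR/SEIR), continuous-time simulation, and percolation-threshold
  estimation.
* The footnote-style alternative reading of the random-walk variant
  (states as link conductances) is not implemented; the measures use
  unit resistances with state weights applied outside the circuit.
* Saturation-time cell values depend on $\beta$, the network draw, and
  the saturation threshold; the harness reproduces the protocol and the
  qualitative winner regimes, and makes no claim of matching any
  particular published table cell by cell.
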