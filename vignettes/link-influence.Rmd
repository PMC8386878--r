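---
title: "Link-based influence maximization under the linear threshold model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Link-based influence maximization under the linear threshold model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limnet)
library(dplyr)
```

## The problem

Classic influence maximization (IMP) asks which $k$ *seed* nodes, activated
with certainty, maximize the expected diffusion spread. That framing fits
viral marketing, but not the setting that motivates this package: a
health-promotion organization is a *fixed* node $s$ in an
inter-organizational network and cannot conscript adopters. What it can do
is build relationships — add directed links $(s, v)$ — and hope that
influence flows along them. Two things distinguish this link-based problem
(LIM) from seed selection:

1. A new link does not guarantee adoption; the target still weighs the
   spreader's influence against everything else it hears.
2. Influence is *relative*. Incoming edge weights are normalized to sum to
   one, so a new link into $v$ dilutes the influence of $v$'s existing
   in-neighbours. Linking to a popular, heavily-influenced node buys only a
   small share of its attention.

Formally, on a weighted digraph $G = (V, E, w)$ with $w(e) > 0$, the
normalized weight of edge $(u, v)$ is

$$ w_n(u, v) = \frac{w(u, v)}{\sum_{x \in N_{\mathrm{in}}(v)} w(x, v)}. $$

Choosing a set $S$ of link targets yields the extended graph with edges
$E^S = E \cup \{(s, v) : v \in S\}$ and renormalized weights $w_n^S$. The
objective $\sigma(S)$ is the expected number of nodes active at the fixed
point of the linear threshold process on that graph, and the task is to
maximize it subject to $|S| \le k$.

## The diffusion model

Each node independently draws a threshold $\theta(v) \sim U[0, 1]$. The
spreader is active at time 0; at every synchronous step, an inactive node
activates when the normalized weights of its already-active in-neighbours
sum to at least $\theta(v)$ (the comparison is inclusive). The process stops
when a sweep changes nothing, after at most $|V|$ steps. `simulate_diffusion()`
runs one trajectory and reports activation times; `estimate_spread()`
averages the final activation count over Monte-Carlo replicates, each
replicate drawing thresholds from its own counter-derived RNG stream so that
any single replicate is reproducible in isolation.

Two conventions worth making explicit, because the quantities reported
downstream depend on them:

* the spreader counts toward the spread, so $\sigma \in [1, |V|]$;
* "fraction activated" divides by $|V|$ including the spreader. On the
  50-node study networks the alternative conventions differ by at most
  $1/50$.

## The exact oracle

Under uniform thresholds the expected spread has a closed form: the sum over
all *simple paths* $\pi$ starting at $s$ of $\prod_{e \in \pi} w_n^S(e)$,
with the empty path contributing 1. `exact_spread()` evaluates it by
depth-first enumeration. Counting simple paths is #P-hard, so this is an
oracle for validation and brute-force optimization, guarded by a 20-node cap
— not a production estimator. Inside the oracle the spreader's in-edges are
dropped: no simple path from $s$ can re-enter $s$, and this realises the
normalization $N^S_{\mathrm{in}}(s) = \emptyset$ assumed by the closed-form
marginal gain.

The marginal gain of one more link has its own closed form,

$$ \sigma(S \cup \{x\}) - \sigma(S) =
   w_n^{S\cup\{x\}}(s, x) \sum_{\rho \in P_x^S}
   \bigl(1 - I^S(\rho)\bigr) U^S(\rho), $$

where $\rho$ ranges over simple paths out of $x$, $U^S(\rho)$ is the weight
product along $\rho$, and $I^S(\rho)$ aggregates the weight products of
paths from $s$ that end at $x$ and can be prepended to $\rho$. Because
$I^S(\rho) \le 1$, every term is nonnegative — which is precisely why
$\sigma$ is monotone; a term-by-term comparison argument extends this to
submodularity. `marginal_gain()` implements the identity, and the test suite
verifies it against the difference of two `exact_spread()` calls to
$10^{-9}$ on exhaustive sweeps. (One published intermediate step writes a
product over paths where its derivation requires a sum; the implementation
follows the sum, which is the reading consistent with the final identity.)

Monotonicity plus submodularity buys the standard greedy guarantee: picking
the argmax of $\sigma(S \cup \{v\})$ one link at a time achieves at least
$1 - 1/e \approx 0.63$ of the optimum. The suite checks that bound on
instances small enough to enumerate (`optimize_links(method = "brute")`).

## GLIM and the baselines

`optimize_links()` implements the greedy (GLIM) with either the exact oracle
or Monte-Carlo evaluation, plus three baselines: static out-degree ranking,
right-eigenvector centrality recomputed on the extended graph after every
addition, and uniform random selection. Design choices that were genuinely
open:

* **Tie-breaking** is everywhere by smallest node identifier (numeric when
  identifiers are integer-like), making exact-evaluator runs fully
  deterministic.
* **Common random numbers**: within one greedy iteration all candidates are
  scored against the same threshold draws. This removes most of the
  between-candidate sampling noise (and with it most of the winner's-curse
  bias in the argmax) at no cost; it is switchable (`common_rn = FALSE`).
* **Reported spread**: the trace re-estimates $\sigma$ of the enlarged set
  on an independent RNG stream after each addition, rather than reusing the
  selection-time maximum, because the max of noisy candidate estimates is an
  upward-biased estimator of the selected set's spread.
* **Eigenvector centrality** is the dominant right eigenvector of the
  raw-weight adjacency of the *current* extended graph (out-influence
  reading), by power iteration from a uniform start, relative tolerance
  $10^{-10}$, 1000 iterations. On acyclic graphs the adjacency is nilpotent
  and no such eigenvector exists; the implementation then falls back to the
  out-degree ranking for that iteration with a warning. The uniform start is
  an exact fixed point on symmetric cycles, where all centralities tie.
* **New-link weight** defaults to 1 — on unit-weight networks the new link's
  normalized weight is $1/d^{\mathrm{in}}$ — but is exposed because the
  theory only requires positivity.

`optimize_seeds()` implements classic greedy seed selection under the same
diffusion model, for contrast. On the packaged `contrast5` fixture the two
problems pick different nodes at budget 1: seed selection takes the most
influential node even though it is heavily influenced, link selection takes
a node whose near-empty in-neighbourhood leaves the new link undiluted. The
fixture is a synthetic reconstruction found by exhaustive search over small
unit-weight graphs (the canonical published example's edge list is only
available graphically); it is labelled synthetic in its documentation.

## Synthetic networks

Six generators, all unit weights, nodes labelled `0..n-1` by arrival:

| type | structure | parameter defaults |
|------|-----------|--------------------|
| `gn` | growing network (tree, DAG) | — |
| `gnr` | growing network with redirection | `p = 0.3` |
| `gnc` | growing network with copying (densest DAG) | — |
| `random_k_out` | every node gets `k` random out-edges; cyclic | `k = 5` |
| `pl_tree` | power-law-degree tree, bidirected | exponent 3 |
| `ba` | Barabasi-Albert, bidirected | `m = 5` |

Choices that the generators' common descriptions leave open, and how they
were resolved here:

* **Edge orientation of the growing networks**: newcomer → ancestor (the
  citation convention). The alternative (ancestor → newcomer) makes every
  non-root GN/GNR node have a single in-edge of normalized weight 1, so the
  whole tree activates with probability 1 from the root and there is nothing
  left to optimize — a degenerate comparison. Under the citation convention
  a node's in-degree is its attachment count, the preferential kernel
  (in-degree + 1) is meaningful, and all spread must be bought through
  diluted links, which is the trade-off the problem studies.
* **GNR redirection** applies after the same preferential pick as GN, so
  `p = 0` reduces exactly to GN; redirection at the root attaches to the
  root itself.
* **Power-law tree**: degrees are iid rounded continuous power-law draws
  (tail $x^{-3}$, minimum 1), rejection-sampled until exactly tree-feasible
  ($\sum d = 2(n-1)$), then assembled as a uniform random tree with that
  degree sequence via a Prüfer sequence. Conditioning rather than repairing
  keeps the advertised tail undistorted.
* **Spreader rule for experiments**: one node drawn uniformly per
  realization (seeded). This matches stated practice for this kind of
  study; the alternative of always seeding at node 0 makes node 0 — the
  dominant hub in a Barabasi-Albert graph — the spreader, which saturates
  the network before any link is chosen and collapses all methods to the
  same curve. `"first"` and explicit identifiers remain available.

## The experiment harness

`run_comparison()` generates `realizations` networks, runs each requested
method to the budget on every realization, and aggregates the
fraction-activated curves (mean and SD per step). Everything derives from
one root seed: realization $r$'s network, its spreader draw, and each
method's evaluation streams. `export_curves()` writes a byte-stable tidy
CSV; `autoplot()` draws the curves with dispersion ribbons.

Problem sizes used in the packaged checks: the theoretical properties
(monotonicity, submodularity, gain identity, Monte-Carlo calibration) are
verified exhaustively on 200 random graphs of up to 7 nodes; the greedy
guarantee on 50 instances with enumerable optima; the six-type comparison at
$n = 50$, budget 15, 200 Monte-Carlo replicates per evaluation and 10
realizations per type — replicate counts scaled down from the 1000 a full
study would use, which widens per-point noise to roughly $\pm 1$ percentage
point on the final mean fraction.

## What the synthetic experiments do and do not show

The generators emulate structural extremes — sparse trees through dense
copying DAGs, cyclic regular out-degree, and bidirected preferential
attachment — with unit weights and uniform thresholds. Real
inter-organizational networks have heterogeneous weights, reciprocated ties
that are not perfectly bidirectional, and threshold distributions nobody
knows; passing tests on generated networks shows the optimizer orders
methods correctly and estimates spread consistently *within this model*,
not that the spread percentages transfer to any particular real network.
On these conditions the greedy reliably dominates the centrality and random
baselines in the directed types, while in bidirected trees the margin over
random selection is small — there, most single links buy similar reach, so
cheap heuristics are nearly as good.

## Known limitations

* The exact oracle is exponential and capped; large-graph exactness (e.g.
  linear-time DAG computation) is out of scope.
* Independent-cascade diffusion, link costs, and non-uniform threshold
  distributions (beyond the pluggable draw function) are not implemented.
* Eigenvector centrality on acyclic extended graphs degrades to the degree
  ranking by construction (with a warning), since no dominant eigenvector
  exists there.
* Monte-Carlo greedy evaluation is $O(\text{candidates} \times
  \text{replicates})$ per step; it is meant for networks of a few hundred
  nodes at most, which is the setting the problem targets.
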