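---
title: "A spectrum of routing strategies: model, costs, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spectrum of routing strategies: model, costs, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(routewalk)
```

## The model

`routewalk` studies communication on weighted undirected networks — the
motivating case is structural brain networks (connectomes), where nodes are
cortical parcels and edge weights are proximities such as streamline or
fiber densities. Messages are modeled as random walkers that must reach a
designated target node `t`. A single non-negative parameter λ tunes how much
*global* information about the topology shapes each step:

$$P_\lambda(Y = j \mid X = i, T = t) \;=\;
  \frac{\exp\{-(\lambda\,(d_{ij} + g_{jt}) + d_{ij})\}}{Z_{it}}$$

Here `d_ij` is the edge distance between neighbors (the local term), and
`d_ij + g_jt` is the shortest distance from `i` to the target through `j`
(the global term; `g` is the geodesic distance). At λ = 0 the walker sees
only local structure and the dynamics are the unbiased random walk
`P(j|i) = w_ij / s_i` — the *reference strategy*. As λ → ∞ all probability
mass collapses onto shortest paths and the expected walk length equals the
geodesic. The target is always an absorbing state. The model therefore
unifies the two classical communication regimes — diffusion and
shortest-path routing — in one family, and lets us price the transition
between them.

Two costs are attached to every source–target pair:

* **Transmission cost** `C_trans(i,t)`: the mean walk length (in edge
  distance) from `i` to `t`, computed analytically from the absorbing
  chain's fundamental matrix `N = (I - Q)^{-1}` as the visit-count-weighted
  sum of each node's expected next-step distance. It can never beat the
  geodesic, and equals it in the λ → ∞ limit.
* **Informational cost** `C_info(i,t)`: the visit-frequency-weighted
  Kullback–Leibler divergence (in bits) between the biased rows and the
  reference rows — the information needed to reshape the dynamics. It is
  identically zero at λ = 0 and grows with the bias.

The two scales are deliberately never mixed: transmission cost is in
natural-log distance units (`d = -ln w̄`), informational cost in bits
(log base 2).

## Weights, distances, and normalization

Raw proximities are mapped onto (0, 1) by the unique affine function that
sends the minimum nonzero weight to ε and the maximum to 1 − ε (default
ε = MIN(w)), preserving edge rank order. Distances are `d = -ln(w̄)`. The
natural logarithm is forced by the λ = 0 identity: only with base *e* does
`exp(-d_ij)` recover `w̄_ij` so that the zero-bias walk is exactly the
strength-proportional random walk. Non-edges carry an explicit `Inf`
sentinel, never a large finite distance, so the support of the transition
model is exact. Disconnected inputs are refused outright rather than
silently reduced to a largest component, because every quantity downstream
assumes the target is reachable from everywhere.

## Numerical choices

* Transition rows are built with a log-sum-exp shift (exponents translated
  by their row maximum) so large λ cannot underflow an entire row; λ on the
  order of hundreds is safe.
* λ = ∞ is a distinct symbolic implementation: probability is restricted to
  the shortest-path neighbor set S and distributed ∝ `exp(-d_ij)` within S,
  which resolves degenerate-path ties exactly (uniform when all distances
  are equal) rather than approximately.
* Membership in S uses the relative tolerance
  `|d_ij + g_jt - g_it| ≤ 1e-9 · max(1, g_it)`. The tolerance is a package
  choice — no canonical value exists for weighted geodesics — and absorbs
  floating-point error without admitting genuinely longer paths.
* `(I - Q)` systems are solved by one dense LU factorization per target
  (serving all sources); singularity is reported as an
  absorption-unreachable error, never patched.
* λ = 0 is special-cased to the exact `w̄/s` rows so the unbiased-walk
  identity, and hence `C_info = 0` at λ = 0, holds exactly rather than to
  one ulp.
* Grand means over pairs use the `N(N-1)` ordered pairs with `i ≠ t`; the
  nodal source/target averages keep the `1/N` divisor of their defining
  formulas (the zero self term included). The choice of divisor cancels in
  all normalized quantities.

## The λ grid and trade-off summaries

The default grid has 60 points uniform in ln λ from −6 to 3.2 — the range
over which the spectrum's interesting behavior unfolds on
connectome-scale networks — optionally extended by the exact 0 and ∞
endpoints. Trade-off curves normalize mean transmission cost by its value
at λ = 0 (its maximum) and mean informational cost by its value at the
largest finite grid point; areas under the normalized curves are trapezoid
integrals over ln λ. The λ = 0 point cannot enter a log-domain integral and
is used for normalization only.

## Null models

Randomized reference networks preserve, of the empirical network: the
binary degree sequence exactly (Maslov–Sneppen double-edge swaps, with
swaps that would disconnect the graph rejected — connectivity is required
by all downstream machinery), the weight multiset exactly (weights are
permuted, never altered), and the strength sequence approximately
(simulated annealing on `C = Σ_i |s_i − r_i|`, Metropolis acceptance
`exp(-ΔC/T)`). The default schedule is 123 stages from t₀ = 100 with the
temperature multiplied by 0.125 after each stage, read literally; that
makes the run effectively greedy after about ten stages, so most of the
schedule is refinement. The per-stage proposal count, which the schedule
itself does not fix, defaults to `E·log(E)` swaps (E = edge count), enough
to mix at desk scale; both the count and the cooling factor are
configurable. On the shipped fixtures the annealed per-node strength
discrepancy lands well under 5% of mean strength.

Empirical cost curves are normalized by ensemble means (`‖C‖`), and nodal
costs are z-scored against the ensemble's nodal distributions with a
two-sided mask at α = 0.01 by default. A node with zero ensemble variance
yields an undefined z and is masked. Note `‖C_info‖` is 0/0 at λ = 0,
where both costs vanish identically.

## Privileged nodes and stretch

The hybrid regime gives the global-information bias to a subset of
*privileged* nodes only; all other rows stay at the reference walk.
Privileged sets are the top fraction of a centrality ranking: betweenness
(on edge distances), strength, shortest-path closeness, random-walk
closeness (inverse mean first-passage steps into the node under the
reference walk), or a seeded random draw. Ties break by ascending node
index, so selections are deterministic.

*Stretch* quantifies what partial information costs: for each source, the
mean over targets of `|C_hybrid(i,t) − g_it|`, with the privileged rows at
their λ = ∞ limit by default. Since non-privileged motion is stochastic,
only expected walk lengths are well-defined, so stretch is read as the gap
between the expected hybrid walk length and the fully informed
shortest-path length; aggregation is over targets for each source node
(source-side, symmetric with the source closeness measures). Both readings
— which walk-length the gap uses, and which side it aggregates over — are
package choices, as no canonical convention exists; fraction 0 and 1
reduce bitwise to the reference and fully biased models, and the
all-privileged stretch is the zero vector.

## Synthetic fixtures

`synth_connectome()` emulates the statistical signature the model is built
for, not any specific parcellation: sparse community structure (default 64
nodes, 4 modules, intra/inter edge densities 0.35/0.06), a few hub nodes
with boosted connection probability, and edge distances that are log-normal
*by construction* — distances are drawn log-normal (meanlog 0.5, sdlog 0.5)
and weights set to `exp(-distance)`, which lands weights in (0, 1)
automatically and mirrors the log-normal synaptic- and projection-strength
distributions reported for cortical connectivity. The default hub boost (6)
is chosen so designated hubs reliably dominate the strength ranking, which
is what the hub-asymmetry analyses presuppose. Draws are fully determined
by the seed; a disconnected draw is retried on an incremented sub-seed.

What the generator does *not* reproduce: empirical degree sequences of any
atlas, spatial embedding and distance-dependent wiring, hemispheric
symmetry, or subject-to-subject variability. Tests passing on these
fixtures therefore validate the machinery and its qualitative behavior
(monotone cost curves, hub source/target asymmetry, null-model contrasts),
not quantitative claims about real connectome cohorts.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script exercise: exact closed forms on
3–4 node paths; brute-force path and walk enumeration oracles on ≤ 9-node
random graphs; Monte-Carlo agreement at 10⁵ walks per (network, λ, target)
triple on ≤ 12-node fixtures; full spectrum curves on 64-node synthetic
connectomes over the 60-point grid; and 20-member null ensembles on 48-node
fixtures. These sizes give sub-minute runs per block while leaving every
statistical check with comfortable power.

## Known limitations

* λ is global (or binary privileged/non-privileged); continuously varying
  per-node λ(i) is out of scope.
* Walks are first-order Markov: no memory of past nodes, no
  time-continuous dynamics, and no congestion or traffic-capacity
  modeling.
* The cost measures assume all node pairs communicate with equal salience;
  on systems where they do not, the measures are upper bounds.
* No efficiency (reciprocal-cost) measure is exported, and no
  communicability- or PageRank-style comparisons are included.
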