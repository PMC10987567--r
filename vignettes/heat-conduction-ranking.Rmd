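---
title: "Heat-conduction ranking of influential spreaders: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heat-conduction ranking of influential spreaders: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcmrank)
```

## The problem

Which nodes of a contact network, if they start spreading something — a
pathogen, a rumour, a product — reach the largest audience? Purely local
scores (degree) miss position; purely global ones (betweenness, closeness)
are expensive and brittle on sparse or modular graphs. The heat-conduction
score combines five structural signals into one number per node, and this
vignette explains the model, its tunable choices, how we validate it
against simulated spreading, and where its guarantees stop.

## The model

Physical heat conduction moves `Q = ΔT · K · A / ΔL` of heat between two
bodies. The network reading used here treats node `i` as a warm body
exporting heat to every other node `j`:

$$Q(v_i, v_j) = \frac{D(v_i)\, e^{EC(v_i)-EC(v_j)}\, \mathrm{Density}(G)\, Dd(v_j)}{R(v_i,v_j)},
\qquad I(v_i) = \frac{1}{N-1}\sum_{j\neq i} Q(v_i, v_j).$$

- the sender's **degree** `D(v_i)` scales its reservoir;
- the **eigenvector-centrality gap** is the temperature difference — heat
  flows more readily towards less central nodes. The exponential keeps the
  factor positive and well-behaved when the gap is negative. `EC` is the
  principal eigenvector of the adjacency matrix scaled to unit Euclidean
  norm, so `Σ EC² = 1`; this normalization is part of the model's
  arithmetic, not a cosmetic choice, because `EC` values enter `Q` through
  an exponent;
- the **network density** `2M/(N(N-1))` plays the conductivity `K`;
- the receiver's **degree density** `Dd` is the contact area: its degree
  spread over a disc whose radius is the hop distance;
- the **hop distance** `R` is `ΔL`.

`I(v_i)` averages over all `N−1` potential receivers; nodes are ranked by
descending `I`.

### The degree-density convention

The disc-area reading of the contact term gives `Dd = D(v_j)/(\pi R^2)`,
hence `Q \propto D_j/(\pi R^3)`. However, the frozen reference values for
the bundled example network (`example_reference()`) — which this package
treats as the authoritative worked example of the method — are only
reproduced by the alternative convention `Dd = D(v_j)/\pi^R`, i.e.
`Q \propto D_j/(R\,\pi^R)`. The two coincide exactly at `R = 1` and diverge
beyond it; on the example network `Q(v_1,v_4)` is `0.294` under the
exponential convention versus `0.231` under the literal disc area, and only
the former matches the reference table. Both are therefore implemented and
exposed as `hcm_config(area_mode = c("exponential", "quadratic"))`, with
**exponential as the default** so that the reference example reproduces
bit-for-bit at printed precision; `run_example(area_mode = "quadratic")`
demonstrates the divergence. Rankings from the two modes usually agree on
the leaders (distance-1 pairs dominate `Q`) but can reorder mid-field
nodes; any report should state the mode used.

### Degenerate inputs and policies

- **Unreachable pairs** (disconnected graphs): `Q` is undefined without a
  distance, so unreachable pairs contribute 0 to the sum while the
  normalizer stays `N−1`. Capacities remain finite and comparable within a
  component; across components they are deflated in proportion to the
  unreachable share, which is the intended reading ("exports nothing to
  nodes it cannot reach"). `largest_component()` is provided for users who
  prefer the giant component.
- **Isolated or zero-degree nodes** export and receive nothing: `Q = 0`.
- **Closeness on disconnected graphs** is computed within each node's
  component with that component's size as `N`; singleton components score 0.
- **Ties in `I`** (possible on vertex-transitive graphs) are broken by
  first-appearance node order, making every ranking deterministic.

## Numerical choices

Eigenvector centrality is computed by power iteration with tolerance
`1e-10` on the max-norm difference of successive normalized iterates and a
1000-iteration cap, erroring (with the residual) rather than returning an
unconverged vector. Iteration runs on `A + I` rather than `A`: the shift
leaves the principal eigenvector unchanged but prevents the period-2
oscillation that raw power iteration exhibits on bipartite graphs. The
result is orientation-fixed (non-negative) and cross-checked against an
independent ARPACK route in the test-suite. Distances are breadth-first
search per source (`O(NM)` total), validated against a Floyd–Warshall
oracle. All structural inputs to `I` are computed once and reused for every
pair, keeping the score `O(N^2)` after the distance pass.

## Spreading ground truth

Rankings are benchmarked against agent-based spreading processes, not
mean-field rate equations:

- **SIR** (`sir_run`, `sir_influence`, `sir_spread`): synchronous
  discrete time; each step every infective node independently infects each
  susceptible *neighbor* with probability `α`, then recovers with
  probability `β`. Infection is processed before recovery, so with `β = 1`
  an infective node gets exactly one infection round. A node's influence is
  the mean number of initially susceptible nodes ever infected when it is
  the sole seed (seeds excluded from the count).
- **Independent cascade** (`ic_run`, `ic_spread`): newly active nodes get
  one attempt per inactive neighbor with probability `p`; activated totals
  include the seeds by default (toggleable).

With `β = 1`, the SIR final-size distribution equals reachability under
independent edge retention with probability `α` — bond percolation — and
the IC model induces the same law. `exact_percolation_influence()` /
`exact_percolation_spread()` exploit this: on graphs with at most 20 edges
they enumerate all `2^M` edge subsets (union-find per subset) and return
the *exact* expected spread, a simulation-free oracle the Monte-Carlo
simulators are tested against at 3 standard errors.

A susceptible node with `k` infective neighbors is infected with
probability `1-(1-\alpha)^k`, drawn as a single Bernoulli rather than `k`
independent ones; the final-size law is identical and the RNG stream
shorter. Randomness is seeded per node and per sweep point via a
deterministic substream derivation from one master seed, so every result
is bit-reproducible and independent of evaluation order. Default `β = 1`
throughout; the `t_max = 30` horizon is a safety cap that, with `β = 1`,
can only bind on graphs of diameter above 30.

## Rank agreement

`kendall_tau()` counts concordant/discordant node pairs between two score
vectors aligned by node identity (never between permutation indices).
Variant `a` is the plain `2(n_c-n_d)/(n(n-1))`; variant `b` applies the
standard tie correction and is the default because Monte-Carlo influence
scores tie heavily at realistic run counts, and τ-a systematically deflates
under ties. When one vector is entirely tied, τ-b's correction is 0/0 and
the statistic is reported as 0 — no ordering information. `tau_curve()`
sweeps τ against SIR influence over `α ∈ {0.01, …, 0.1}` by default;
`resort_curve()` lists ground-truth infection values in a candidate's rank
order and counts ascents — zero ascents means perfect agreement.

## What the synthetic generators do and do not show

Tests and experiments run on the bundled 11-node example plus
Erdős–Rényi and Barabási–Albert graphs (`generate_er`, `generate_ba`),
which stand in for real networks at desk scale. They exercise correctness —
oracle equivalences, percolation exactness, invariances — on graphs with
tens of nodes, and BA graphs supply heavy-tailed degrees. They do *not*
emulate the community structure, degree correlations, or clustering of real
social and collaboration networks, so a high τ here does not by itself
predict the score's accuracy on such data; it certifies that the
implementation computes the model correctly and that the model tracks exact
spreading influence on the structures tested. Test problem sizes (graphs of
10–50 nodes, `10^3`–`10^4` Monte-Carlo runs, the 16-edge exact enumeration)
were chosen to make every check exact or statistically sharp while keeping
the default suite fast.

## Known limitations

- The score is a static one-shot formula, not an iterated heat diffusion;
  no dynamics over time are modelled.
- Dense `N × N` intermediates (distance matrix, pairwise gaps) make memory
  the binding constraint around `N ≈ 2 \times 10^4`.
- Weighted, directed, and temporal graphs are out of scope, as are
  approximate betweenness sampling and influence-maximization seed
  optimization (seeds always come from rankings).
- The exact percolation oracle is deliberately capped at 20 edges;
  beyond that, Monte Carlo is the only ground truth.
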