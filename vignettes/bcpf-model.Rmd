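---
title: "Coupled structural balance and bounded-confidence opinion dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled structural balance and bounded-confidence opinion dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcpf)
```

## The model

`bcpf` simulates a population of `N` agents on a *complete signed network*:
every pair `i, j` carries a sign `s_ij = +1` (friends) or `s_ij = -1`
(enemies), and every agent holds an opinion vector `x_i` in `[0,1]^F` on
`F` issues.  Two classical dynamics are coupled:

**Structural balance (Heider).**  A triad `ijk` is balanced when
`s_ij * s_ik * s_jk = +1`: either all three are friends `(+++)` or two
friends share a common enemy `(+--)`.  Each time step one of the
`N(N-1)(N-2)/6` triads is drawn uniformly at random.  Balanced triads are
left alone.  An all-enemies triad `(---)` resolves by turning one enmity
into friendship; a `(-++)` triad resolves, with probability `p`, by turning
the enmity into friendship and otherwise (probability `1-p`) by breaking
one friendship.  A complete signed network is balanced if and only if it is
a single clique of friends or two mutually hostile cliques (the *bipolar*
state), and balance is absorbing for the signs.

**Bounded-confidence opinions (Hegselmann–Krause), friends only.**  Every
`M = round((N-1)(N-2)/6)` time steps one uniformly chosen agent revises
its opinion to the arithmetic mean (issue by issue, itself included) of the
opinions of its *friends* whose opinion distance is at most the confidence
level `epsilon`.  Enemies never influence an agent.  A *round* is `N * M`
steps, so on average each triad and each opinion is revised once per round.

**The coupling: preferential flip.**  Which link flips in an unbalanced
triad is decided by the opinion distance
`Delta_ij = max_f |x_{i,f} - x_{j,f}|` (Chebyshev; a Euclidean option is
provided): in `(---)` the *closest* pair becomes friends, and in the
`1-p` branch of `(-++)` the *most distant* friendship breaks.  Opinions
thus shape the network while the network gates opinion influence.

The absorbing states follow the random-flip classification: for `p < 1/2`
the network ends bipolar, for `p > 1/2` all-friends; `p = 1/2` is the
critical point, accepted but flagged.  Within each final clique, opinions
end in one or more internally identical clusters; across cliques the
opinions segregate (low opinions in one clique, high in the other, for
`F = 1`).

Baselines implemented alongside the preferential rule: `ltd` (random flip,
Antal et al.'s local triad dynamics), `ctd` (random candidate applied only
if the global unbalanced-triad count does not increase; runs can jam), and
`bc` (opinion updates on a fixed all-friends network).

## Parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `N` | agents | 40 | the headline experiments use 40 |
| `F` | issues per agent | 1 | 2 for the bi-dimensional analyses |
| `p` | friendship-forming probability in `(-++)` | 0.1 | must lie in (0,1) |
| `epsilon` | confidence level | 0.2 | `[0,1]`; 0 freezes opinions |
| `rho0` | initial positive-link probability | 0.5 | i.i.d. per pair, not a quota |
| `metric` | opinion distance | chebyshev | euclidean optional |
| `flip_rule` | link selection | preferential | random / constrained |
| `opinion_update_period` | steps between opinion updates | `round((N-1)(N-2)/6)`, floor 1 | the cadence is not integer for all `N`; rounding keeps the one-opinion-per-`(N-1)(N-2)/6`-triads average while staying deterministic |
| `max_rounds` | cap before a run is declared non-absorbed | 1e6 | estimators use much smaller caps, see below |
| `tol_fixedpoint` | per-sweep opinion convergence | 1e-10 | |
| `tol_cluster` | opinion-equality tolerance for counting | 1e-6 | |

A `--stochastic-schedule` variant updates an opinion after each triad step
with probability `opinion_rate * 6/((N-1)(N-2))`; `opinion_rate = 2`
doubles the average opinion-update speed, which leaves the absorbing
behavior essentially unchanged.

## Design choices in the open corners

*Asynchronous updates.*  The opinion rule is stated as an average over the
neighborhood, but the schedule revises one agent at a time; the revised
agent reads the current state.  After the network balances, the signs are
frozen forever, and the run continues with one random-agent opinion
revision per tick.  Every `N` ticks a *non-mutating* probe computes the
prospective change of every agent; the run is absorbed when no agent would
move by `tol_fixedpoint` in a full revision sweep.  This matters: revising
agents in whole random permutations (a seemingly innocuous alternative)
synchronizes the extremes and measurably lowers the consensus threshold of
the pure bounded-confidence baseline (to ~0.35 instead of ~0.5 at
`N = 40`).

*Tie-breaking.*  When two pairs share the extremal distance (exactly equal
doubles), one is chosen uniformly from the run's single RNG stream.  Ties
are measure-zero at initialization but become common once clusters form.

*Termination and snapping.*  Network balance alone does not end a run;
asynchronous averaging only converges asymptotically, so opinions are
iterated to the `1e-10` fixed-point criterion and then snapped to their
cluster means (tolerance `1e-6`) for reporting.  The unsnapped values are
retained.

*Indices.*  Agent indices are 1-based everywhere (API, CSV files, logs),
following the host language's convention.

*Near-absorption snapshot.*  Each absorbed run stores the opinion matrix
from one `N`-tick block before per-block opinion motion first fell below
`1e-6`.  This is the natural place to observe cluster-level opinion
alignment: members of a forming cluster approach their common limit along
the covariance's leading eigendirection, so their scatter is nearly rank
one shortly before it collapses to a point.

*Seeds.*  One RNG stream per run, seeded from `params$seed`; ensembles
derive the seed for run `r` of cell `c` as `base_seed + (c-1)*runs +
(r-1)`, so every printed summary is exactly reproducible.

## Heavy-tailed balance times, and the caps used by the estimators

Balance times are strongly heavy-tailed, and understanding why is useful
when choosing run caps.  For `epsilon = 0` (frozen opinions) the median
time to balance grows roughly as `log T ~ 0.6 N` (measured at
`N = 10..28`), which is desk-scale at `N <= 25` and ~1e11 steps at
`N = 40`.  For intermediate `epsilon` a run is a race: if the network
balances within a few rounds (the typical case at `epsilon >= 0.1`,
`N = 40`), the run absorbs quickly; if instead the opinions first freeze
into three or more mutually distant clusters, the preferential rule keeps
breaking exactly the inter-cluster friendships a bipartition would need,
and balance waits for a rare fluctuation.  At very large `epsilon` a
different slow tail appears: opinions nearly merge globally, distances
degenerate, and the preferential rule loses its guidance.

The ensemble tools therefore run with explicit caps and report the
absorbed fraction; medians and means are computed over absorbed runs only.
The problem sizes used by the shipped estimators and acceptance checks:
`max_rounds = 2000` at `N = 30..40`, `200` for the large segregation
batches, `500` for the bi-dimensional batches at `N = 20`, and `50` at
`N = 100`, where no stalls were observed in 1000 runs.  The random-flip
(LTD) baseline at `N = 40` does not absorb on a desk at all (its balance
time grows super-exponentially), so the convergence-time comparison against
it uses right-censored medians: the preferential rule's median sits at a
few rounds while every random-flip run is still unbalanced at the cap.

## What the estimators measure

- `estimate_consensus_threshold(..., model = "bc")`: smallest grid
  `epsilon` at which *every* run of the all-friends baseline ends in a
  single opinion.  With the study's 8-runs-per-value protocol this
  estimator is noisy: the per-run fragmentation probability is only
  ~7-10% over `epsilon = 0.35..0.45`, so "all 8 runs reach consensus" can
  fire one or two grid steps before the probability truly vanishes
  (around 0.5).
- `estimate_consensus_threshold(..., model = "bcpf")`: smallest grid
  `epsilon` at which every absorbed coupled run ends with exactly one
  opinion per clique (two in the system); lands at 0.20-0.25 for
  `N = 40, p = 0.1`.
- `estimate_p_threshold()`: classifies absorbed runs as bipolar vs
  all-friends over a `p` grid and returns the midpoint of the bracketing
  interval, ~0.5.
- `estimate_Ttyp()`: median steps (and rounds) to balance over seeds,
  undefined (flagged) when fewer than half the runs absorb.

## What the synthetic initial conditions do and do not emulate

Initial states are i.i.d.: each link positive with probability `rho0`,
each opinion uniform on `[0,1]`.  That matches the study conditions but
not, for example, empirically observed sign correlations (real signed
networks are already largely balanced) or clustered opinion landscapes.
Passing tests therefore certify the dynamics' behavior from generic random
starts; behavior from structured starts (e.g. an already balanced network
with opinions scattered independently of the cliques, where opinion
segregation between cliques need not arise) is exercised only by the
user-supplied-state interface.

## Known limitations

- Only complete networks; no link weights, no repulsion from enemies'
  opinions, no Deffuant-style pairwise updating.
- The hyperplane-separability check is exact for `F = 2` (convex-hull
  disjointness) and uses a minimum-distance quadratic program with a tiny
  ridge for `F > 2`; the alignment score is defined for `F = 2`.
- Separability of the two cliques' opinion sets in absorbing states holds
  in over 99% of bi-dimensional runs but is not universal: rarely an agent
  ends as an isolated one-agent opinion cluster frozen strictly inside the
  opposing clique's hull, a counterexample to a blanket "always".
- Opinion-count curves near cluster-merge boundaries can shift by one
  cluster with the counting tolerance (`tol_cluster`).

## A worked micro-example

```{r example}
res <- run(bcpf_params(N = 40, p = 0.1, epsilon = 0.2, seed = 1))
res
head(res$series)
```

The run ends bipolar with one opinion per clique; `D_plus = 0` signals
intra-clique consensus, and `D_minus` close to one half reflects the two
cliques sitting near opposite quarters of the opinion interval.
```{r cliques}
sapply(res$partition, function(cl) mean(res$opinions[cl, 1]))
```
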