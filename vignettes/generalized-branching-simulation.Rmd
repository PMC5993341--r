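---
title: "Simulating phylogenies under generalized branching processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating phylogenies under generalized branching processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bhtree)
```

## The model

`bhtree` simulates species trees forward in time under a generalized
Bellman–Harris branching process. A single origin lineage arises at time 0
(the stem age). Every lineage carries two competing clocks:

* a **waiting time to speciation**, drawn from an arbitrary distribution
  (`waitsp`), and
* a **waiting time to extinction**, drawn independently from a second
  arbitrary distribution (`waitext`; omitted = no extinction, i.e. an
  infinite waiting time).

Whichever clock rings first decides the lineage's fate; on a tie (possible
only with point-mass clocks) speciation wins, which favours tree growth.
Because the clocks need not be exponential, speciation and extinction
probabilities may depend on species **age** — the process is a renewal
(Bellman–Harris) process, not a Markov birth–death chain. Classical models
are special cases:

| model | waitsp | waitext |
|---|---|---|
| Yule | `rexp(lambda)` | none |
| constant-rate birth–death (crBD) | `rexp(lambda)` | `rexp(mu)` |
| Bellman–Harris (BH) | any | none |
| BH with extinction (BH-ex) | any | any |

A Weibull speciation clock with shape tending to 0 approaches the
proportional-to-distinguishable-arrangements regime in which each labelled
topology on *n* tips is equally likely.

### Speciation modes

Because lineage ages matter, the model must say who is "new" at a
speciation event:

* **symmetric** (default): both daughters are new species of age 0; each
  draws fresh speciation and extinction clocks; the mother terminates at
  the event (she becomes the internal node).
* **asymmetric** (budding): one daughter is new (age 0, fresh clocks); the
  mother persists with her original age and — crucially — her original
  scheduled extinction time. After each budding she draws a fresh
  speciation waiting time measured from the event, and buds repeatedly
  until a drawn speciation time would fall beyond her extinction time.

Under exponential clocks the two modes generate identical tip-count
distributions (memorylessness); under age-dependent clocks they behave very
differently. The package's point-mass regression case — speciation always
after 2 Myr, extinction always after 2.5 Myr, run to age 5 — illustrates
this: symmetric mode doubles the lineage count at t = 2 and 4 (counts
1, 2, 4), while asymmetric mode oscillates (counts 1, 2, 1, 2, 1 with
transitions at 2, 2.5, 4, 4.5) and ends with a single survivor.

### Lineage-specific shifts

With probability `shiftsp$prob` (`shiftext$prob`), a **newly formed**
species draws a scaling factor *f* from a strength distribution
(`shiftsp$strength`), and from then on its speciation (extinction) waiting
times are drawn from the base distribution and multiplied by *f*. The
factor is inherited by all descendants until another shift occurs. Shifts
model heritable changes in diversification propensity (key innovations,
released antagonists); *f* < 1 accelerates the process, *f* > 1 slows it.

Two readings of "shift on top of shift" are possible; the package default
**replaces** the inherited factor (each shift is defined relative to the
base distribution, which is how the per-node bookkeeping of factors stays
interpretable). A multiplicative reading is available behind
`compound_shifts = TRUE`. The origin lineage always carries factor 1 and is
never shift-tested: shifts are defined for species formed *at* speciation
events, and the origin is not. Both choices are deliberate resolutions of
genuinely open corners of the model description.

## Waiting-time grammar

Specs are written exactly as one would invoke the corresponding R random
generator, minus the leading "number of observations" argument:
`"rexp(0.5)"`, `"rweibull(0.4,3)"`, `"rgamma(1.5,1,2)"` (positionally
shape, rate, scale — a third argument overrides the rate, mirroring the
positional convention), `"runif(0.5,1.5)"`, `"rlnorm(0,1)"`,
`"rnorm(2,0.5)"` (truncated to positive values by resampling), and
`"const(2)"` for a deterministic waiting time. Omitted trailing parameters
take the generator defaults (`"rweibull(0.4)"` means scale 1). Any function
returning one positive waiting time per call is also accepted.

Numerical edge policy: a drawn waiting time that is zero, negative or
non-finite is resampled (up to 100 times, then an error), because
zero-length waits would stall the event loop in an infinite cascade of
simultaneous events. Distributions with some mass at or below zero are
therefore legal but are implicitly conditioned on positivity; `const(0)`
always errors.

## Stopping conditions

* `sim_age(age, config)` runs to a fixed stem age; lineages alive at `age`
  become extant tips. Status is `"extinct"` if nothing survives,
  `"single_survivor"` if exactly one species survives *and* the tree is
  pruned (`complete = FALSE`), otherwise `"completed"`.
* `sim_taxa(n, config)` stops the first time `n` lineages coexist and cuts
  the tree exactly at that speciation event, so the two newest tips have
  zero-length pendant edges. First-passage stopping biases towards young
  trees, so `sim_taxa(n, config, gsa = TRUE, m = ...)` implements the
  general sampling approach: simulate until `m` (≫ `n`; the simulation is
  clipped at the *first* passage to `m`, the minimal reading that keeps
  cost bounded) lineages coexist, collect all time intervals during which
  exactly `n` lineages coexist, and cut at a time drawn uniformly over
  their union (interval chosen proportionally to length, then uniform
  within). Intervals of zero duration — transient counts inside an instant
  of simultaneous point-mass events — carry no measure and are excluded.
  No guidance exists for choosing `m` beyond `n ≪ m`; we expose it as a
  required argument and suggest `m ≥ 10 n` without enforcing it.
  Realizations that die out before reaching the target are redrawn, up to
  `retry_cap` (default 10,000) attempts, so extinction-dominated
  configurations fail loudly rather than hang.

## Trees, pruning, sampling

Simulation results carry both the full per-lineage record table
(`$lineages`: origin, scheduled extinction, realized end, fate, factors,
flags — retained even when no tree is returned) and an assembled `bh_tree`.
Under symmetric speciation each event is an internal node with the two
daughters as children; under asymmetric speciation each budding event is an
internal node with the mother continuing on one child edge. The stem edge
(origin to first event) is kept and exported as a Newick root edge.

`prune_extinct()` removes all lineages without extant descendants and
suppresses degree-2 nodes, summing edge lengths exactly; the pruned,
unsampled tree is ultrametric (verified to 1e-9 relative tolerance in the
tests). `sample_tips()` models incomplete sampling: `round(N·frac)` tips
(round half up, minimum 2 — the description gives no rounding rule) kept
either uniformly or by successive draws without replacement weighted by
current pendant branch lengths. Because its contract requires an all-extant
tree, `sim_config` rejects `frac < 1` combined with `complete = TRUE`.

Internal event times are plain doubles compared exactly (no epsilon):
times are sums of draws, and the only exact ties that matter arise from
point-mass specs, where exactness is wanted. Simultaneous events across
lineages are processed in ascending lineage-id order, making runs bitwise
reproducible under a fixed seed.

## Batches, statuses, estimators

`run_batch()` seeds replicate *k* with `substream_seed(master, k)` (a
Lehmer-style hash modulo 2³¹−1), so any replicate can be reproduced in
isolation. `summarize_batch()` reports medians and central 95% intervals
of tip counts and oldest branching times, excluding extinct replicates
from shape aggregates (the cross-validation protocol) while tallying all
statuses. The age-stopped status codes follow the 0/1 convention of the
original interface but as named statuses (`"extinct"`,
`"single_survivor"`) rather than sentinel integers; with `complete = TRUE`
a lone survivor still yields a full (completed) tree, since the
single-survivor code is defined only for pruned output.

`estimate_event_rates()` computes the counting-process estimators: pooled
speciation (extinction) events divided by pooled alive lineage-time. It
pools over *all* replicates' lineage records, including fully extinct ones
— conditioning on survival would bias the estimators — which is why the
records are retained on every result.

## What the generator emulates, and what a green test establishes

The synthetic regimes used throughout the tests are the stated worked
examples of the model family: Yule with rate 0.5 (taxa-stopped, n = 20),
crBD with rates 0.9/0.1 at age 4, age-dependent Weibull(0.4, 3) clocks,
shifts with probability 9% and uniform [0.5, 1.5] strength, and the
point-mass 2 / 2.5 Myr traces. They exercise age-dependence, both
speciation modes, extinction, shifts and both stopping rules, but they are
still idealized: no diversity- or trait-dependent rates, no rate changes
through time, no fossilized sampling, and the shift strengths are bounded.
A green suite establishes that the engine reproduces the analytic limits
(Yule/crBD means, rate recovery, mode equivalence under exponential
clocks) and the deterministic traces — not that any particular empirical
clade is well described by these models.

Test budgets are kept by scaling replicate counts down (e.g. 2,000–4,000
where 10⁴ would be ideal; 400–1,000 replicates for the two-mode
cross-validation comparison); every stochastic assertion is
standard-error-aware (4 SE) or a distribution test at α = 0.01, so
scaling down only widens the acceptance bands.

## Known limitations

* The event loop is pure R; it is comfortable at desk scale (thousands of
  trees with hundreds of tips) but not tuned for single trees with 10⁵
  tips.
* GSA clips at the first passage to `m`; later returns of the count to `n`
  (after the process first exceeded `m`) are not eligible cut regions.
* Proportional tip sampling defines weights as current pendant lengths at
  each successive draw; other weighting conventions exist.
* `read_newick()` infers extant/extinct marks from tip depth relative to
  the deepest tip (1e-9 relative tolerance), which is correct for trees
  cut at a common horizon but not for arbitrary non-ultrametric inputs.
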