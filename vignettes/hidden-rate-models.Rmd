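---
title: "Constrained and hidden-rate Markov models for binary traits on chronograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained and hidden-rate Markov models for binary traits on chronograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitmk)
```

## The model and its assumptions

traitmk treats a binary character on a rooted, time-calibrated phylogeny as
a continuous-time Markov chain running independently along every branch.
Branch lengths are taken as absolute time — no unit conversion is applied —
so all rates are in events per time unit of the input chronogram. The
generator $Q$ has non-negative off-diagonals and zero row sums, and the
transition kernel over a branch of duration $t$ is $P(t) = e^{Qt}$.
Polytomies are handled natively (the pruning product simply runs over more
than two children) and zero-length branches contribute an exact identity
kernel; both arise in published chronograms and neither is rewritten.

Three layers of structure sit on top of the basic chain:

* **Parameter sharing.** A model spec maps every permitted off-diagonal
  cell to a free-parameter index; equal indices share one rate, index 0 is
  a structural zero. The named families (ER, ARD, IND, ARD_loss and the
  hidden-rate combinations) are just particular maps, and `make_spec(
  "custom", index = ...)` accepts any other map, so constrained hypotheses
  need no new code.
* **Hidden rate categories.** With `R = 2`, the state space is expanded
  category-major to (observed state, regime). Regime switches connect the
  same observed state across regimes — a lineage never changes its trait
  and its regime in one jump — with either distinct $R1\to R2$ / $R2\to R1$
  rates or a single shared rate. Category switching is
  observed-state-independent (one switch rate pair for all states); this is
  the only parameterization consistent with the free-parameter counts of
  the published model families this package mirrors (e.g. binary ER/ER has
  $1+1+2=4$ rates, the joint ER/ARD with shared switching $1+8+1=10$).
* **Joint two-trait coding.** Two binary characters become one 4-state
  character in the fixed order $(0,0), (0,1), (1,0), (1,1)$ of
  (trait1, trait2). Cells changing both traits at once are structural
  zeros: correlation enters only through rates depending on the other
  trait's background, never through simultaneous jumps. `ARD_loss` ties
  the $(0,1)\to(0,0)$ rate to the $(1,1)\to(1,0)$ rate, the likelihood-
  ratio-style question "is trait-2 loss independent of trait 1?" expressed
  as one fewer parameter.

Missing tip states are all-ones partial vectors (exact marginalization). A
species missing either character of a joint analysis is kept with a fully
missing 4-state vector rather than dropped, so the AICc sample size $n$
stays the tip count of the one tree used across all models of a
comparison.

### Root policies and clamps

The root weight vector is either flat over expanded states, or fixed to an
observed state. With hidden categories a fixed root splits its mass
uniformly over that state's $R$ regimes: the analysis fixes only what is
observable, and uniform is the least-informative completion of the
unobservable regime. This is a genuine modelling choice — another software
package may renormalize differently, shifting hidden-model log-likelihoods
by a small constant — and it is deliberately confined to `root_vector()`.

A clamp zeroes, at one internal node, every expanded state whose observed
state differs from the required one, and keeps all regimes of the required
state (the clamp constrains the trait, not the tempo). A clamp that makes
the data impossible returns $-\infty$ rather than throwing, so model
searches over clamps stay total. Clamping the root under a flat prior
equals fixing the root up to an additive $\log(R/m)$ — a tested
consistency between the two mechanisms.

## Numerical choices

* **Matrix exponential.** One eigendecomposition of $Q$ is shared across
  all branches; each kernel is validated (finiteness, near-stochastic rows)
  and any branch failing falls back to scaling-and-squaring
  (`arma::expmat`). Entries are clamped into $[0,1]$ and rows renormalized.
  The contract — agreement with the analytic 2-state solution and the
  Chapman–Kolmogorov identity to $10^{-10}$ — is what the tests enforce;
  the algorithm behind it is free to change.
* **Pruning with per-edge rescaling.** Partial-likelihood vectors are
  rescaled by their maximum at every edge with the log-scale accumulated,
  so trees of hundreds of tips cannot underflow; log-space arithmetic
  throughout would be slower for state spaces of at most 8.
* **Optimization.** Rates are fitted on the log scale within
  $[10^{-9}, 10^{2}]$ by `nlminb` (relative tolerance $10^{-8}$, 500
  iterations). Start 1 is a parsimony heuristic — Fitch changes divided by
  total tree length — and further starts are drawn log-uniformly over
  $[10^{-5}, 10]$, a deliberate subrange of the bounds: starts at
  $10^{-9}$ waste evaluations in a flat likelihood region. All per-start
  optima are kept in the result so multimodality is visible, and a fit is
  flagged `converged` when the best two starts agree within $10^{-4}$
  log-units. Fits accept extra warm starts (`init =`), and the package's
  own tests warm-start richer models from nested models' optima — that is
  how the nested-likelihood inequalities (ARD never below ER; a clamped
  fit never above its unclamped family) are guaranteed numerically rather
  than statistically.
* **AICc.** $-2\ln L + 2k + 2k(k+1)/(n-k-1)$ with $n$ the number of
  terminal taxa of the analysed tree — the only $n$ that reproduces the
  published model-comparison tables this design follows. For toy trees
  with $n \le k+1$ the correction is undefined and the fit stores `NA`.

## Marginal reconstruction and transition counting

The marginal posterior of a node is computed by clamping that node to each
observed state and renormalizing the resulting log-likelihoods
(log-sum-exp). This is algebraically identical to the classical up–down
(re-rooting) pass but shares one code path with everything else — root
policies, user clamps, hidden categories, missing tips — and its
$O(\text{nodes}^2)$ cost is negligible in the compiled core at the few-
hundred-tip scale this package targets. Hidden-category mass is summed
into observed states before reporting (`expanded = TRUE` exposes the full
expanded marginals).

Transition counts are an *interpretation* of the marginal map, not a
sufficient statistic, so they are reported as ranges: each node gets its
MAP state; a branch whose endpoints disagree is a change; changes touching
a node with MAP probability below the threshold (default 0.7) — or an
exact tie, which is never broken arbitrarily — only enter the upper bound.
Stochastic character mapping, which samples full histories instead, is out
of scope. The worked example in the README shows the consequence: the
total change count brackets the simulated truth, while the split between
gains and losses can be genuinely undecidable from tip data under a
misspecified single-regime model.

## The synthetic world

`simulate_tree()` grows a pure-birth (Yule) tree — the root splits at time
zero, each lineage splits at rate $b$, and the present is one further
waiting time after the $n$-th lineage — then rescales to the target height.
`simulate_traits()` runs the exact Gillespie algorithm along every branch
and records every event, including regime switches, with absolute
timestamps, so parameter-recovery and transition-count tests compare
against a known truth. `make_fixture()` assembles a 292-tip, height-200
chronogram with two binary traits generated under two-regime hidden-rate
models: a rare trait (~10–20% present at the tips, exactly 6 species
recoded as missing) and a commoner one (~20–30%), echoing the shape of the
turtle mental-gland / macrohabitat dataset that motivated the design
(292 species, 6 unknown gland states). One seed drives tree and traits
through derived streams (`seed`, `seed+1`, ...), so each part regenerates
independently and bit-identically.

What the generator does *not* emulate: extinction (no birth–death),
diversification–trait interactions, phylogenetic uncertainty (one fixed
tree), sampling biases in which species get measured, and misidentified
tips. A green recovery test therefore establishes statistical correctness
of the estimator under the assumed model on clean ultrametric trees — not
robustness to the many ways real comparative datasets violate it.

## Known limitations

* At most two hidden regimes, two traits, and 4 observed states; no
  branch-specific or time-varying $Q$; no Bayesian machinery.
* Transition tallies depend on the MAP threshold; for rare scattered
  states the gain/loss split can flip between plausible interpretations
  (see above) even when the total is stable.
* Parameter recovery for the 7-parameter joint `ARD_loss` model from tip
  data alone is noticeably weaker than for the 1–2 parameter binary
  models at comparable event counts: individual rate MLEs can collapse to
  the boundary when every event of a transition type is overwritten before
  reaching a tip. The acceptance suite measures and reports this rather
  than hiding it.
* The fixed-root regime completion (uniform over hidden categories) is one
  of several defensible conventions; comparisons of hidden-model
  log-likelihoods across software should expect small additive offsets.
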