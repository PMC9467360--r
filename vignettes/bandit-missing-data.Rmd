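---
title: "Simulating two-armed bandit trials with missing binary outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating two-armed bandit trials with missing binary outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(banditmiss)
```

## The model

A two-armed trial enrols `n` patients sequentially. Arm `k` (control `k =
0`, experimental `k = 1`) has an unknown Bernoulli success probability
`p_k`. After each patient is assigned, their binary outcome is generated
from the assigned arm's `p_k`; independently of the outcome, it is *missing*
with the arm's missingness probability `pm_k` (missing at random within arm:
the masking depends only on the assigned arm, never on the outcome itself,
and `pm_k` is capped at 0.5 — larger rates are unrealistic in a trial
setting). Each arm carries a Beta posterior starting from a uniform
Beta(1, 1) prior; observed successes and failures update it, missing
outcomes do not. The allocation rule sees only the posterior states, so a
missing outcome leaves the rule's view of that arm — and hence its next
decision about it — frozen.

Operating characteristics are estimated by Monte Carlo over independent
replications:

* `E[p*]` — the expected proportion of patients assigned to the experimental
  arm, `p* = N_1/n`. Under a null configuration (`p_0 = p_1`) a symmetric
  rule has `E[p*] = 0.5`; response-adaptive rules aim to push it above 0.5
  under the alternative.
* ONS — the observed number of successes (missing and imputed outcomes
  excluded).
* ENS — the oracle expected number of successes, counting the true values of
  missing outcomes as well. The engine retains those true values solely for
  this tally; they never reach any policy.
* The per-arm bias of the terminal sample mean and its covariance identity
  (below).

## The allocation rules

Ten rules are implemented, selected by name in `trial_config()`. With
policy-facing Beta state `(a, b) = (s0 + S, f0 + F)` (imputed outcomes
included in `S`, `F` when imputation is on) and `q_k` the posterior
probability that arm `k` has the larger success probability:

| rule | allocation |
|------|------------|
| FR   | randomize with probability 1/2 (Thompson exponent `c = 0`) |
| TTS  | randomize with `pi_k` proportional to `q_k^c`, `c = t/(2n)` |
| RTS  | as TTS with `c = 1` |
| RPW  | urn draw; success adds a ball of the treated arm, failure of the other arm, missing none |
| CB   | argmax of the posterior mean `a/(a+b)` |
| GI   | argmax of the Gittins index `G[a, b]` at discount `d = 0.99` |
| UCB  | argmax of `a/(a+b) + 2 log(t) / (a+b)` |
| RandUCB | argmax of `a/(a+b) + Z/(a+b)`, `Z` uniform on 20 equally spaced points in `[0, 1]` |
| RBI  | argmax of `a/(a+b) + Z·K/(a+b)`, `Z ~ Exp(mean K)`, `K = 2` |
| RGI  | argmax of `G[a, b] + Z·K/(a+b)`, same `Z` |

Exact index ties are broken uniformly at random, which makes the first
allocation an equal randomization for every rule. `P(p_a > p_b)` for the
Thompson rules is evaluated with the exact finite-sum identity for
integer-parameter Beta distributions in log space; inside the trial engine
it is updated incrementally (one Beta parameter changes per observation), so
Thompson allocation costs O(1) per patient. Both routes are tested against a
quadrature oracle.

Three conventions deserve a note, since different readings exist in the
literature:

* The UCB bonus is `2 log(t)` times `1/(a+b)` — not the `sqrt(2 log t)` of
  classical UCB1, and the scale `1/(a+b)` counts observations (plus prior
  pseudo-counts), not `1/sqrt(n_k)`. This variant is taken literally from
  the rule set this package implements; it is the combination under which
  the package reproduces the reference operating characteristics (e.g. UCB
  allocating ~34% to the experimental arm under control-arm missingness 0.5
  in the null scenario with `p = 0.9`, `n = 200`).
* RandUCB's support distribution is uniform over its `M` points — the
  parameter-free choice; `M = 1` with `L = U = beta` recovers UCB.
* The perturbations `Z` of RandUCB, RBI and RGI are drawn independently per
  arm per step (the follow-the-perturbed-leader convention).

## Computing the Gittins index

`compute_gittins_table()` computes `G[s, f]` for every integer state with
`s + f <= max_total` by retirement-value calibration: the index of a state
is the retirement reward `lambda` at which continuing the arm and retiring
on `lambda` forever are equally valuable. Values come from backward
induction on the state space truncated at a horizon `T` with
`d^T/(1 - d) <= tol` (for `d = 0.99`, `tol = 1e-5`, `T = 1604`).

One backward-induction pass at a fixed `lambda` yields the continuation
value of *every* table state, together with its derivative in `lambda`
(retired states contribute `1/(1-d)`, continued states propagate the
discounted expectation). The calibration gap is convex, decreasing and
piecewise linear in `lambda`, so a single ascending sweep over a 512-point
grid brackets all roots simultaneously, and the Newton tangents at the
bracket ends bound each root from below while the chord bounds it from
above — a certified enclosure per state from shared passes. States whose
enclosure is wider than `refine_tol` (kinks near the root; they concentrate
at deep states along the `s = 1` / `f = 1` edges) are re-solved by
synchronized bisection. The resulting table records its achieved
`precision` (half the widest remaining enclosure; about 2.5e-4 at the
default settings for `max_total = 530`, with shallow states far more
accurate — the uniform-prior state is good to ~1e-6 and matches the
published four-decimal value 0.8699 at `d = 0.99`). Simulated allocation
decisions are insensitive to this residual: perturbing the whole table by
±2.5e-4 leaves `E[p*]` unchanged to Monte-Carlo precision. An independent
brute-force recursive dynamic program backs the tests at small discounts,
and tables survive a plain-text round trip via `write_gittins_table()`.
Within a session, `cached_gittins_table()` reuses the last table per
`(d, tol)` whenever its coverage suffices.

## The trial engine

`run_replications()` simulates all `R` replications in lockstep, one patient
at a time, on plain vectors — the idiomatic-R substitute for a compiled
per-patient loop; a cell of 10^4 replications at `n = 200` takes on the
order of a second. Per patient the engine draws, in a fixed order:
perturbations (if the rule uses them), the allocation uniform, the outcome,
the missingness mask, and an imputation uniform (always drawn, even with
imputation off). The fixed order gives common random numbers: two runs with
the same seed differing only in the imputation setting see identical outcome
and missingness streams, and with no missingness at all they are identical
outright — both facts are asserted in the tests. A scalar reference engine,
assembled step by step from the exported policy operations with the same
draw order, must reproduce the vectorized engine bit for bit at `R = 1` for
every rule; this pins the fast path to the documented semantics.

All replications of one call share a single RNG stream seeded once from
`config$seed` (rather than per-replication child streams); re-running with
the same seed is bit-identical, and `run_trial()` is exactly
`run_replications()` with `R = 1`.

Two ledgers are kept per arm. The policy-facing ledger contains prior plus
observed plus imputed counts and is all any rule ever sees. The
observed-only ledger (`S`, `F`, `M`) feeds the metrics and the imputation
estimate. Mean imputation replaces a missing outcome, at the moment it goes
missing, by a Bernoulli draw at the arm's current observed success rate
`S/(S+F)`, or at `impute_initial` (default 0.5) while the arm has no
observed outcomes. Two published variants are available: a large initial
estimate (`impute_initial = 0.9`) and imputation only after the first
observed outcome (`impute_after_first = TRUE`). Whether the estimate should
feed imputed values back into itself is genuinely open; the default uses
observed-only counts, with `impute_source = "filled"` as the alternative —
in the scenarios we examined the two differ by a few percentage points of
`E[p*]` at most.

## Bias of the sample mean under adaptive sampling

Adaptive allocation couples the number of patients an arm receives to how
well it appears to be doing, which biases the terminal sample mean
`phat_k = S_k/(S_k+F_k)` downward for under-sampled arms. The bias obeys

    Cov[N_k, phat_k] / E[N_k] = p_k - E[phat_k]

`bias_and_covariance()` estimates both sides with Monte-Carlo standard
errors (delta-method for the identity gap). Two caveats the implementation
is explicit about: with missing outcomes, `N_k` counts patients whose
outcome was never observed, and the identity holds exactly only for the
observed count `S_k + F_k`; and replications where an arm has no observed
outcome are excluded from that arm's summaries (and counted). Because
`S = 0` whenever `S + F = 0`, the identity restricted to the included
replications is still exact — the tests verify it for every rule, under a
null and an alternative scenario without missingness, at the protocol's
replication counts.

## Scenario grids and reproduction scale

`trial_scenarios()` carries the twelve benchmark designs (five null
scenarios at `n = 200`; seven alternatives with `n` chosen for 90% power
under equal allocation), `missingness_grid()` the 16-combination set (equal
rates 0–0.5, control-only, experimental-only) and the full 6 × 6 grid, and
`build_grid()`/`run_experiment()` the resumable cross-product runner with
per-cell seeds derived by a stable hash — adding cells never perturbs
existing ones. Replication defaults follow the protocol: 10^4 per cell,
10^3 for TTS. The full 12 × 16 × 10-rule grid is reproducible but takes a
few hours on one CPU; the test suite and the acceptance script instead pin
the headline single cells (the Fig-2-style extreme null `p = 0.9`, the
S6/S12 contrast, the S12 imputation contrast) at full replication counts,
plus the seven alternative scenarios at 10^3 replications per missingness
combination — desk-scale choices that keep the whole suite within tens of
minutes while leaving every Monte-Carlo standard error far below the
tolerances being checked.

## What the generator does and does not emulate

The generator reproduces the study conditions exactly as specified:
independent Bernoulli outcomes, arm-wise MAR masking with rates up to 0.5,
fully sequential allocation with immediate (or never) outcome availability.
It does not emulate delayed outcomes, covariates or covariate-driven
(informative) missingness, staggered or batched enrolment, or early
stopping. Conclusions drawn from passing tests therefore concern the rules'
behaviour under ideal MAR missingness; real trials with informative
missingness or delays are outside what these simulations can confirm.

## Known limitations and sensitivities

* Two arms are hard-wired; the types carry `K` for clarity only.
* In large-`p` alternative scenarios (e.g. `p = (0.8, 0.9)`), `E[p*]` for
  the index rules is driven by how long the inferior arm survives the index
  race, which is sensitive to the deep-state exploration bonus: with zero
  bonus (CB) we measure `E[p*] ≈ 0.59` at `n = 526`, with the `d = 0.99`
  Gittins bonus `≈ 0.83`, and more explorative randomized rules reach
  `≈ 0.89`. Published figures for such scenarios can therefore differ by
  several percentage points between implementations whose index tables
  differ only in the deep states, even when the shallow-state values agree
  to four decimals.
* Mean imputation at the default initial estimate 0.5 is aggressive for
  high-`p` arms: an early imputed failure can trigger a lasting wrong
  selection for exploitative rules. This is the intended object of study,
  not a defect, but it makes imputed-run summaries in large-`p` scenarios
  the most implementation-sensitive quantities in the package.
* The Gittins table's certified precision is a worst-case bound attained at
  deep edge states whose neighbouring values differ by an order of magnitude
  more; it is not the typical error.

## A worked example

```{r example, eval = FALSE}
cfg <- trial_config("CB", p0 = 0.9, p1 = 0.9, pm0 = 0.5, pm1 = 0,
                    n = 200, seed = 1)
summarize_replications(run_replications(cfg, R = 10000))
```

Under the null with half the control arm's outcomes missing, the greedy
current-belief rule assigns about 63% of patients to the experimental arm —
missingness alone, non-informative by construction, skews a greedy rule's
allocation; UCB in the same cell goes the other way (~34%). The package
exists to quantify exactly these effects.
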