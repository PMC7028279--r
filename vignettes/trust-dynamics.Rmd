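---
title: "Trust, Theory-of-Mind planning and disruption dynamics in a pharmaceutical supply chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trust, Theory-of-Mind planning and disruption dynamics in a pharmaceutical supply chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7, fig.height = 4)
library(pharmsim)
library(dplyr)
```

## The model

`pharmsim` simulates a stylized three-echelon pharmaceutical supply chain as a
discrete-time multiagent system. The default network has six agents — two
manufacturers, two distributors, two healthcenters — with each distributor
supplied by exactly one manufacturer and each healthcenter ordering from both
distributors. One manufacturer ("Disrupted MN") suffers a capacity-reduction
disruption; the distributor it supplies is "Disrupted DS". One healthcenter
("Trust HC") splits its orders across distributors in proportion to the
trustworthiness it attributes to them; the other ("Equal HC") splits equally.

The system is a Markov game: at each time-step every agent picks an action,
a shared deterministic transition advances the joint state, and each agent
receives a reward. Manufacturers and distributors pay holding and backlog
costs and are rewarded per unit shipped; healthcenters pay holding and
backlog costs and are rewarded per patient treated. All quantities are
non-negative reals (a fluid model): nothing in the dynamics requires
integrality, and rationing rules stay exact without rounding artifacts.

### Ordering and allocation

Every agent orders (or produces) by an order-up-to (base-stock) rule: the
target is

$$S = f \,(l + 1) + s\, f,$$

where $f$ is the forecast demand per step (the most recently observed
demand: patient demand for healthcenters, orders received for upstream
agents), $l$ the replenishment lead time (2 steps between echelons, 0 for
production) and $s$ the safety-stock fraction (default 0.5). The order is
$\max(0, S - \text{position})$.

The **inventory position** counts on-hand stock plus shipments actually in
transit, minus the agent's own backlog. It deliberately does *not* credit
quantities a supplier has failed to ship: an unserved buyer restates its
whole outstanding requirement every step. A seller's per-buyer backlog is
therefore the most recently restated requirement net of what it has shipped
— unmet demand rolls forward (and can re-route to the other supplier, or
shrink once the shortage passes) instead of being double-billed. This
behavioral convention is what lets a capacity shock amplify into the
order-variance oscillations and post-shock excess inventory characteristic
of the bullwhip effect; with full credit for supplier backlog the network
returns to steady state almost passively and no destabilization can occur.

Scarce sellers ration by one of two rules: **proportional** (pro-rata to
requests) or **preferential** (the preferred buyer is served fully first).
Healthcenters split their order either **equally** or **by trust** (pro-rata
to attributed trustworthiness, falling back to an equal split when all trust
is zero so the rule stays total-preserving).

### Trust

Each healthcenter tracks, per distributor, an on-time delivery rate $D$: the
mean over the last $w$ steps (default $w = l + 1 = 3$) of the per-step
fulfillment ratio $\min(R_k/E_k, 1)$, where $E_k$ is what was due at step
$k$ (orders arrive after the promised lead time) and $R_k$ what actually
arrived. Steps with nothing expected count as fully met, and early or excess
delivery cannot raise the ratio above 1, so $D \in [0,1]$ always and a fully
reliable supplier scores exactly 1. Trustworthiness is the exponential
smoothing

$$T_t = (1 - \delta)\, T_{t-1} + \delta\, D_t,$$

with sensitivity $\delta \in [0,1]$. Under a constant rate $D = d^*$, $T$
converges to $d^*$ geometrically with ratio $1-\delta$; higher $\delta$
reacts more strongly to recent performance and oscillates more under
alternating delivery patterns. Trust starts at 1 and stays there through an
undisrupted warm-up.

### Theory-of-Mind planning

A planning agent (in the shipped scenarios only "Disrupted DS") chooses
among its allocation rules by rolling the world forward $H = 6$ steps
(enough for a three-echelon chain with lead time 2 to show the consequences
of a decision) and maximizing its discounted return with $\gamma = 0.9$.
Three modeling commitments matter:

* **Disruption blindness.** The rollout uses nominal capacities and mean
  demand: agents have no model of disruptions, so mid-disruption plans are
  optimistic about upstream supply. The rollout state consequently diverges
  from reality exactly while a disruption is active.
* **Greedy opponent models, nested one level.** Other agents are modeled as
  following their decision rules (and, if they plan, as best-responding with
  everyone else scripted). Mutual best response is resolved by a single
  sequential pass in a fixed canonical agent order; with one planning agent
  this is exact. The rollout includes the trust updates and split rules of
  the healthcenters, so the planning distributor anticipates how its
  allocation moves the trust attributed to it and hence future order routing
  — this anticipation is what makes it shed its volatile customer during a
  shortage.
* **An indifference threshold.** The planner deviates from the earlier
  action in canonical order (proportional before preferential) only when the
  alternative improves the planned return by more than `tie_tol` (default
  2%). Strict floating-point ties essentially never occur, so a bare argmax
  would let numerically trivial differences drive systematic behavior; with
  the threshold, the distributor develops a preference only when trust
  dynamics give it something material to exploit, and is rationally
  indifferent (hence proportional) when the healthcenters' behavior offers
  no leverage — including the limit of an insensitive (low-$\delta$) or
  equal-splitting buyer.

The discount exponent is the planning depth: a reward $h$ steps ahead is
weighted $\gamma^h$, the standard finite-horizon convention (a factor
depending on wall-clock time alone would not affect any argmax).

### Disruptions

A disruption multiplies one manufacturer's capacity by $1-\text{severity}$
for `breadth` consecutive steps. The three named profiles remove (almost)
the same total capacity: short (84% x 10), moderate (42% x 20), long
(17% x 50); the long profile's total differs by about 1%, as specified.
Nominal capacity defaults to `capacity_factor = 1.1` times steady-state
production. The factor matters structurally: all three profiles must push
effective capacity below steady throughput (which requires a factor below
$1/(1-0.17) \approx 1.2$, otherwise the long profile never binds and mild
long disruptions would be costless), while the undisrupted manufacturer
needs headroom to ramp production when demand shifts toward it — the
mitigation channel that distinguishes long from short disruptions. A 10%
margin satisfies both.

## Scenarios and accounting

`run_scenario()` warms the network up until every order and shipment series
is constant (relative change below `1e-6` for 5 consecutive steps — the
network is initialized at its analytic steady state, so this resolves
immediately), schedules the disruption 5 steps later, and simulates through
the disruption and its aftermath. Costs for comparisons are holding +
backlog only (throughput rewards are part of agents' objectives, not of the
cost metric), summed from disruption onset to the end of the run, and
percent changes are ordinary relative changes against a baseline run in
which both healthcenters split equally.

Two windows are used. The default run length after onset is four breadths
(the disruption plus a three-breadth tail); scenario-versus-baseline
comparisons and the sensitivity sweeps use it. For comparisons *across*
disruption profiles the episode is instead measured over a common window of
200 steps after onset (four times the largest breadth): comparing cumulative
costs over windows of different lengths would confound disruption profile
with accounting span.

## What the defaults emulate — and what they do not

Patient demand is constant at 100 units per healthcenter per step (the
normal-demand generator with configurable mean/SD exists for robustness
runs); costs are holding 1, backlog 10, shipping reward 5, treatment reward
10 per unit — backlog deliberately an order of magnitude above holding, as
stockouts in pharmaceutical supply chains are harm, not inconvenience. These
are stylized study conditions: single product, one disruption per run, no
perishability, pricing, contracts, or capacity expansion, and agents observe
the true network state (no belief updating). Passing the directional tests
below shows the *mechanisms* — trust-mediated order switching, planner
customer-shedding, profile-dependent mitigation — are reproduced; it does
not calibrate magnitudes to any real shortage data.

## Numerical choices and degenerate inputs

* Quantities are validated non-negative after every transition (tolerance
  `1e-9` for float drift).
* All-zero requests ship zero (no division by zero); an all-zero trust
  vector splits equally.
* Steps with no expected delivery count as fulfillment 1 in $D$; pre-history
  is padded with met expectations.
* The stabilization detector errors, naming the still-moving series, if the
  network has not settled within `max_warmup` steps (e.g. under stochastic
  demand with a zero tolerance).
* Ties in the planner break to the first action in canonical order:
  proportional before preferential, preferred buyers in declaration order,
  equal before trust-weighted.

## A short run

```{r s1-run, eval = FALSE}
run <- run_scenario(scenario_config("S1"))
glance(run)
autoplot(run)
plot_trust(run)
```

The S1 run (no planning) shows the canonical sequence: the disruption
starves "Disrupted DS", the trust "Trust HC" attributes to it collapses,
orders shift to "Not-Disrupted DS", and the trust-splitting healthcenter
ends the episode cheaper than its equal-splitting peer. With planning
enabled (S2), "Disrupted DS" instead serves "Equal HC" preferentially during
the shortage and the trust-splitting healthcenter is worse off — the
qualitative reversals, sweep trends and profile orderings are exercised by
the test suite (`tests/testthat/test-acceptance.R`) and recomputed end to
end by `scripts/acceptance.R`.

## Problem sizes

The shipped experiments use the six-agent network with demand 100, warm-up
of about 10 steps, and 40-200 steps after onset depending on the window
above; the planner explores $3^6$ action sequences per decision. Oracle
tests run the planner against exhaustive search on the same network at
horizons 1-3, and property tests randomize hundreds of transition steps on
miniature fixtures with analytic steady states (`make_fixture()`).

## Known limitations

* Only healthcenter-to-distributor trust is modeled; upstream agents are
  trusted implicitly.
* The planner's opponent models are exact copies of the true rules; model
  misspecification and learning are out of scope.
* Percent cost changes are ordinary relative changes; they cannot fall
  below -100% while costs are non-negative, so the comparison metric is
  asserted by sign, not magnitude, in the reproduction suite.
* One disruption per run; profiles with recovery ramps or stochastic onset
  are not represented.
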