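---
title: "Scheduling surgeries with penalty-minimizing metaheuristics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scheduling surgeries with penalty-minimizing metaheuristics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`orsched` treats surgical scheduling as a constrained assignment problem.
An *instance* holds N waiting-list surgeries and a set of K *slots* — one
shift of one operating room (OR) on one day, reserved for a single
specialty — over a half-open planning horizon of H days (days are 0-based
integers; calendar dates are mapped to day indices at ingest). Waiting-list
entry days may be negative: the patient joined the list before the period
being planned, which is how backlog pressure enters the model.

A *schedule* maps each surgery to a slot and a position within it, or to
the unscheduled state. Hard constraints, all enforced by
`check_feasibility()`:

* per-slot capacity in minutes, where every assigned surgery charges its
  duration **plus its turnover time** (room cleaning/preparation). We
  charge turnover for every surgery, including the last of a shift: the
  room must be reset before it is handed back, and a single uniform rule
  keeps capacity accounting order-independent. A configuration that waives
  the final turnover would only enlarge every slot by one turnover and
  changes nothing structural.
* an optional per-slot cap on the number of surgeries
  (`max_surgeries`, unbounded by default — minutes are normally the
  binding constraint);
* strict specialty matching: each specialty manages its block of ORs
  independently, so a surgery may only occupy a slot reserved for its
  specialty, and cross-specialty borrowing is not modeled;
* one assignment per patient per period.

Quality is the penalty score
\(pt = \sum_i p_i\) with \(p_i = \max(0, d_i - ds_i)\, w(pr_i)\):
days overdue past the guaranteed-maximum-response-time deadline, weighted
by priority. The product form follows the operational reading "days
overdue times priority"; a subtractive form f(ds) − f(pr) can go negative
and would reward scheduling low-priority surgeries late, contradicting the
idea that only overdue surgeries *earn* a penalty. We take the day part as
identity and the priority part as a configurable weight map, default
`c("1" = 1, "2" = 2, "3" = 4, "4" = 8)` — geometric doubling so that one
day late on an urgent case outweighs a week late on a routine one. The
scale of priority levels and weights differs between hospitals, so the map
is configuration, not a claim about any particular institution.

Unscheduled surgeries contribute zero to `pt` and are reported in their own
column — a penalty score of 0 with a handful of unscheduled cases is a
meaningful and common outcome, because some surgeries exceed the length of
every shift and can only be handled as exceptional cases outside the
ordinary process. For *optimization*, however, a zero charge would make
"unschedule everything" optimal, so the solvers minimize

\[ \text{objective} = pt + U \cdot n_{\text{unscheduled}}, \]

with the per-unscheduled cost defaulting to \(U = H \cdot \max_w\): as
expensive as the worst single-surgery lateness the horizon can produce, so
scheduling a surgery — even overdue — is always preferred to dropping it,
while reported penalty scores stay on the familiar `pt` scale. `U` is
configurable through `solver_control(unscheduled_cost = )` and
`total_penalty(unscheduled_cost = )`.

## Initial solution

`order_waiting_list()` sorts by priority (descending), then waiting-list
entry day (ascending), then id — a deterministic, fully reproducible order
combining medical urgency with waiting-list longevity.
`first_fit_assign()` then places each surgery into the first slot of its
specialty with room for it. Slots are scanned day-major (day, then room,
then id): the earliest feasible day is also the one that minimizes
days-overdue, so the scan order and the objective agree. Remaining
capacity is tracked in minutes after each placement; there is no repacking
or backtracking — it is pure first fit. A `random` mode reshuffles the
scan order per surgery under a seed and is used to diversify restarts.

## Neighbourhood and solvers

All local search runs on one neighbourhood: from a feasible schedule,
either **swap** two surgeries between different slots or **relocate** one
surgery (scheduled or unscheduled) into a different slot with room for it.
Two refinements matter in practice:

* when a direct swap does not fit, the displaced partner may land in any
  third slot with room (an ejection), or — if the mover is unscheduled —
  simply trade places with the occupant. Both variants still change at
  most two assignments, and the place-trade is count-neutral, so no move
  ever reduces the number of scheduled surgeries. Without the trade
  variant, instances whose optimum exchanges a scheduled surgery for an
  unscheduled one are unreachable from a first-fit start.
* proposals are *guided*: half the draws pick the moved surgery among
  those currently paying a penalty (or unscheduled), and a penalized
  surgery prefers target slots earlier than its current day. Guidance
  reshapes only the proposal distribution; feasibility checking and the
  acceptance rules are untouched. Uniform proposals spend almost all draws
  on on-time surgeries whose relocation is irrelevant, and stabilization
  then takes several times longer.

Infeasible candidates are rejected at proposal time (up to a bounded number
of redraws per proposal); the particle swarm instead repairs at decode.
Solvers therefore never emit an infeasible schedule, and every returned
schedule passes `check_feasibility()` by construction.

One **iteration** of hill climbing and simulated annealing is a sweep of N
proposals, making traces comparable across instance sizes.

**Hill climbing** accepts a candidate iff it does not worsen the objective
(Δ ≤ 0). Accepting equal-cost moves lets the search walk across plateaus —
rearranging on-time surgeries at no cost until capacity opens for an
overdue one — and is exactly the zero-temperature limit of the annealer's
acceptance rule, so HC and SA share one acceptance family. The best trace
is monotone non-increasing. `hill_climb_restarts()` adds diversification:
each restart first-fits a seeded random permutation of the waiting list
with randomized slot scanning and the best result across restarts wins.

**Simulated annealing** accepts worsening moves with probability
exp(−Δ/T) under geometric cooling `T ← 0.95 T` per sweep, floored at
1e-6. The default initial temperature is calibrated, not fixed: we sample
candidate moves from the initial solution and set T0 so the mean worsening
delta is accepted with probability ≈ 0.8 (the classic
initial-acceptance-ratio rule). Tying T0 to the initial *objective* value
instead fails on overloaded instances: the objective (~10⁴–10⁵) sits
orders of magnitude above typical move deltas (~10¹), the acceptance ratio
stays pinned at 1 for the whole run, and the annealer never leaves the
random-walk regime. The best-ever schedule is tracked separately from the
current one and is what the solver returns, so excursions cannot worsen
the result.

**Particle swarm** searches a continuous encoding with one coordinate per
surgery: the day-major index of its slot in [0, K−1], with K as the
"unscheduled" sentinel. Decoding rounds and clamps each coordinate, then
repairs to feasibility by first fit among slots sharing the target's day
and specialty, leaving unplaceable surgeries unscheduled; decoding the
encoding of a feasible schedule reproduces its day assignment exactly. The
swarm is the canonical global-best form with constriction-equivalent
constants (inertia 0.7298, cognitive = social = 1.4961) — the standard
defaults where no problem-specific tuning is claimed. PSO starts from
random positions rather than a constructed initial solution, which is the
main reason it trails the local-search solvers on this problem.

### Numerical and degenerate-input choices

* Ties in the waiting-list order and the slot scan are broken by id, so
  every result is reproducible bit-for-bit from (instance, control).
* All stochastic choices of a run flow from one seeded generator;
  callers' RNG state is saved and restored.
* A schedule over zero surgeries or zero slots is legal everywhere
  (validators return empty reports; solvers return the input).
* Within-slot positions are bookkeeping (contiguous, 0-based); the
  objective is day-level, so sequencing within a shift carries no cost.
* An infeasible schedule passed to `total_penalty()` is still scored but
  flagged; solvers refuse infeasible initial schedules outright.

## The synthetic generator

No hospital extract ships with the package; all experiments run on
synthetic instances designed to reproduce the *shape* of an overloaded
surgical centre:

* **Scale.** The default spec pits 198 obesity, 133 urology and 98
  pediatric-plastic surgeries against 122, 89 and 45 slots — demand
  exceeds the slot count in every specialty, the regime in which
  scheduling order actually matters.
* **Durations** are log-normal (median 120 min, log-sd 0.45) truncated to
  [30, 480] by resampling — right-skewed with a heavy tail of long
  procedures, the canonical shape of surgical case-time distributions.
  Estimated durations in practice derive from central summaries of
  historical times; the distribution family here is a package choice, not
  an empirical fit.
* **Slots** are 480-minute shifts; each specialty owns
  `ceiling(n_slots / H)` dedicated rooms filled day-major over a 130-day
  horizon. **Turnover** defaults to a constant 15 min.
* **Priorities** are drawn with probabilities (0.35, 0.35, 0.2, 0.1) for
  levels 1–4 — most of a waiting list is routine. **Deadlines** derive
  from priority via response windows (270/180/60/14 days for levels 1–4),
  loosely modeled on guaranteed-maximum-response-time regimes; entry days
  are uniform on [−180, −1], so part of the backlog is already near or
  past its deadline.

`generate_planted_instance()` inverts the construction: slots first, then
surgeries drawn and packed into them, deadlines set to the planted day
plus a slack of 0–14 days, entry days back-computed from the response
windows. The planted schedule is feasible with penalty 0, and since
penalties are non-negative the instance's optimal score is *certified* to
be 0 — brute force confirms this on small instances, and the construction
proof carries it beyond. `generate_manual_baseline()` emulates a manual
comparison schedule: first fit under an entry-date-only ordering (ignoring
priority), then a fraction of surgeries displaced to later feasible slots.

What the generator does **not** emulate: correlation between duration and
priority or specialty-specific duration profiles, day-of-week and seasonal
slot patterns, cancellations and re-entries, surgeon/anesthesiologist
availability, and emergency arrivals. Tests passing on these instances
show the optimization machinery is correct and effective under realistic
load and deadline pressure; they do not show that any particular
hospital's penalties would drop by a particular amount.

## Problem sizes used in the tests

The test suite verifies, among others: exact agreement with exhaustive
enumeration on 50 random instances of ≤ 6 surgeries and ≤ 3 slots (hill
climbing with 20 restarts on every instance; annealing on ≥ 90% of them);
recovery of the planted zero-penalty optimum on a 100-surgery/40-slot
instance from a plain first-fit start, with stabilization within 100
sweeps; and the qualitative solver ranking HC ≤ SA ≤ PSO in median
objective over 20 seeds on the full 429-surgery/256-slot default instance
at 100 sweeps (40 swarm iterations for PSO). The acceptance script
re-runs the planted-instance computation end to end under a caller-chosen
seed.

## Known limitations

* The day-level objective ignores within-day sequencing quality (e.g.
  surgeon idle time); positions are recorded but not costed.
* Cross-specialty borrowing of OR time is not modeled by design.
* Duration uncertainty is not modeled: estimated minutes are treated as
  exact, so there is no overtime risk term.
* The per-unscheduled cost U is a modeling device for the solvers; when
  comparing objectives across configurations, hold U fixed.
* Hill climbing's plateau walk has no cycle detection; it relies on the
  seeded proposal stream for diversity, which is sufficient in practice
  but carries no theoretical guarantee.
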