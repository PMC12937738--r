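---
title: "Disruption/restoration scheduling of day-hospital surgery: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disruption/restoration scheduling: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`surgsched` schedules a waiting list of day-hospital (DH) elective patients
into operating-room (OR) days discretized into 15-minute slots, and builds,
*together with* the nominal schedule (NS), one restoration schedule (RS)
per enumerated disruption scenario. The design premise is that a pediatric
teaching hospital cannot dedicate an OR to emergencies and suffers frequent
same-day cancellations, so the recovery plan must exist before the
disruption does.

## Penalties

Each patient carries a clinical deadline $l_i$ (days), days already waited
$m_i$, and the urgency weight $u_i = 360/l_i$ (kept as an exact fraction so
$u_i l_i = 360$ holds for any integer deadline). Scheduling $i$ on day $d$
costs $p_{id} = (d + \max(m_i + d - l_i, 0))\,u_i$; exclusion costs
$q_i = (m_i + |D| + 1 + \max(m_i + |D| + 1 - l_i, 0))\,u_i$. Two
properties matter and are tested: $q_i > p_{id}$ for every in-horizon day
(exclusion is never cheaper), and $p_{id}$ increases with $d$ (patients are
pulled forward). The printed equations are typographically ambiguous about
the scope of $u_i$; we adopt the whole-expression weighting (both terms are
"weighted by surgical priority") and expose the alternative
(`penalty_weighting = "tardiness_only"`) as a configuration switch.

## Decision structure

Binary $x_{idj}$ assigns patients to (day, OR). On the protected prefix
$W$ of the horizon (one day in all shipped configurations) the model also
decides the within-day ordering: position variables $y$, precedence
variables $\nu$ (we read $\nu_{irgj}=1$ as "$r$ precedes $i$", the only
direction consistent with the start-time equation
$\xi_{igj} = \sum_r t_r \nu_{irgj} + x_{igj}$), start slots $\xi$
(1-based), per-OR completion $C$, and a per-moment availability machinery
($\rho$, $\lambda$, $\Xi$) that tells, for every 0-based moment $h$,
whether each OR is empty and when it next frees up. Note the deliberate
convention split: *moments are 0-based, start slots are 1-based*.

Emergency scenarios are all triples (moment $h$, protected day $g$, length
class $\gamma_l \in \{4, 8, 16\}$ slots); an emergency must go to the
first-available OR, displaced electives (only those *starting after* $h$)
reappear within $\Delta = 7$ days, and the disrupted day may use up to
$\Omega = 4$ slots of overtime while the emergency consumes
$\min(\gamma_l, T - h)$ slots. No-show scenarios are pairs (patient $b$,
day $g$): a pre-designated substitute per OR — a patient nominally
scheduled on day $g+1$ — fills the gap, and $b$ returns exactly
$\hat\Delta = 2$ days later (a within-$\Delta$ window mode is provided as
an alternative).

## Corrections the printed formulation needs

Three defects surfaced during implementation; each is applied in the model
and mirrored in the validator.

1. **Substitute anticipation.** The no-show anticipation ban, as printed,
   also forbids the substitute's own move from day $g+1$ to day $g$ —
   making every realistic instance infeasible. We split the ban: strict
   for days after $g$; on day $g$ itself, exempt exactly the *activated*
   substitute (the one designated for an OR on which the no-show patient
   actually sits, linearized with auxiliary binaries
   $z \le \theta,\; z \le x$). Without the activation restriction the
   optimizer pulls substitutes forward even in scenarios where nobody
   cancels on their OR, which is visibly wrong in the plans.
2. **Empty-OR availability.** The availability $\Xi$ of an empty OR is
   otherwise a free variable, which lets the solver claim a busy OR is
   "first available". We pin $\Xi = h$ once the OR has emptied. At $h=0$
   the printed machinery is inherently loose (no surgery spans moment 0),
   so every OR counts as first-available there.
3. **Completion upper band.** $C$ is pinned from below by the last
   surgery's end and from above only via the emptiness disjunction at the
   *next integer moment*; when the day is full no such moment exists and
   $C$ floats. The validator accepts the exact admissible band rather than
   requiring equality.

## Solution procedure

The complete model is far too hard to solve monolithically, so the
pipeline is sequential: (1) solve the nominal assignment problem; then
reach a complete feasible solution by either the **warm-start** route (pin
the protected-day admissions of $x^*$ with $\sum_j x_{igj} \ge \sum_j
x^*_{igj}$, keeping the $\ge$ so capacity may still be exploited) or the
**heuristic** route (minimize the number of patient-day differences from
$x^*$, then pin and re-optimize the penalties); then (7) optimize the
emergency plans — which also settles the ordering —, (8) fix the ordering,
and (9) optimize the no-show plans. Emergencies come first deliberately:
their management needs the ordering, which no-show management ignores.

**Backend and the probe.** The backend contract (create variables, add
linear constraints, set objective/limits, solve, report incumbent and
bound) is fulfilled by HiGHS through SciPy's MILP interface in a `python`
subprocess. It accepts no incumbent hints, so the warm start is realized
by *probing*: solve once with $x$ fixed to $x^*$ (cheap — the scenario
subproblems decouple) and note that, because the complete feasible region
is nested inside the nominal one, a probe incumbent matching the nominal
optimum is *provably optimal* for the complete solve, and a
zero-difference probe is provably optimal for the difference step. Only
when the probe is infeasible (which genuinely happens when the whole list
fits on day 1, leaving no day-2 substitute) does the expensive cold solve
run.

**Consistency freeze.** The printed procedure leaves unprotected-day
assignments free in steps 7-9, which could leave the final no-show plans
referencing a different nominal schedule than the emergency plans. We
freeze the full assignment after the complete solve; step 9 additionally
freezes the emergency plans (with $x$ fixed the two plan sets share no
variables, so this is a pure reduction, not a restriction).

**Tiered plan optimization.** Cold incumbent-finding on the complete model
routinely exhausts small time budgets, so step 7 runs up to three solves:
an all-binaries-fixed probe (an LP — an incumbent is always recovered), an
ordering-fixed solve (scenarios decouple; reaches optimality in seconds at
benchmark sizes), and the full ordering-free solve only when the per-step
budget exceeds 120 s. A deterministic *drop repair* then places any
patient flagged as dropped although room exists in their recovery window —
always an improvement, since exclusion penalties dominate assignment
penalties — so that plans surviving validation never waste capacity.

## Numerical choices

* $\varepsilon = 0.5$ in the impact constraint (any value in $(0,1)$ works
  because starts and moments are integers).
* Big-M $= \max(\text{capacity}) + \Omega + 1$, the smallest constant
  covering all disjunctions.
* $|S| = \lfloor \max T_{dj} / \min t_i \rfloor$ positions (floor:
  positions are integral and the bound is attained only by minimum-length
  patients).
* The no-show objective's printed normalization $1/(|I|/|D|)$ is
  dimensionally odd but harmless (a positive scalar does not move the
  argmin); it is implemented as printed with an override.
* Integer feasibility tolerance $10^{-6}$ throughout the validator.
* Boundary ties ($h$ exactly at a surgery end, $h = C$) are accepted in
  either reading by the validator, matching the model's freedom.

## The synthetic generator

`generate_instance()` emulates the benchmark design: lists of 40-120
patients over 14/28-day horizons with 2-3 ORs, $T_{dj} = 24$ slots of 15
minutes, weekends (day indices divisible by 6 or 7) blocked, five urgency
classes with deadlines 30/60/90/180/360 days, and four surgical-length
mixes (A short-skewed, B long-skewed, C uniform, D bimodal) plus a
54-patient case-study mix skewed toward urgent classes. The published mix
histograms are not numerically tabulated, so the shipped distributions are
documented stand-ins and everything is overridable; no acceptance check
depends on their exact values. Days already waited are drawn uniformly on
$[0, \lceil 0.8\,l_i \rceil]$ so the tardiness terms are exercised by
near-deadline patients. The generator uses a private seeded RNG stream
(byte-identical instances per seed, caller's RNG untouched).

What a green run does *not* establish: the generator draws i.i.d. patients
with deterministic durations — no duration uncertainty, no arrival
process, no correlation between urgency and length, no beds/downstream
resources. Conclusions about real waiting-list dynamics need real data.

## Scale and test budgets

With the open-source backend on one CPU, complete-model cold solves at
$|I| \ge 20$ need minutes, not seconds. The shipped tests therefore run
the stated acceptance predicates at reduced scale (fewer seeds, 20-30 s
per-step limits, coarse gaps); the probe/tier machinery guarantees
feasible, validator-clean bundles even at those budgets. The oracle
equivalence criterion runs at its full stated scale (50 tiny instances,
exact agreement).

## Known limitations

* One disruption per day, enumerated scenarios only; no probabilistic
  weighting of scenarios.
* The warm-start route can be genuinely infeasible on lists that fit
  entirely into the protected day (no day-2 substitute exists); the
  heuristic route, or `allow_dummy_substitute`, are the escape hatches.
* Ordering re-optimization in step 7 is skipped under tight budgets
  (tiering above); plans are then optimal *given* the incumbent ordering.
* Reported lower bounds for probe-accepted steps are inherited from the
  nominal relaxation; they are valid but can be loose when step 1 itself
  stopped at a gap.
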