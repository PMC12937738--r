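# surgsched

Elective surgery scheduling for pediatric day-hospital (DH) units, with
ready-to-deploy back-up schedules for every modelled disruption.

## The problem

A pediatric surgery department keeps a waiting list of DH patients. Each
patient *i* has an estimated surgical duration (in 15-minute slots), a
clinical deadline *l<sub>i</sub>* (days), days already waited
*m<sub>i</sub>*, and a compatibility mask over (day, operating room) pairs
(weekends are blocked). The department must build a **nominal schedule
(NS)**: an assignment of patients to days and ORs over a 2-4 week horizon,
plus the within-day ordering and start times on the first ("protected")
day(s).

Pediatric DH units are heavily disrupted: emergencies break into ORs, and
last-minute cancellations (no-shows) are far more common than in adult
surgery. Instead of reserving slack or re-optimizing online, this package
pre-computes one **restoration schedule (RS)** per enumerated disruption
scenario, jointly with the NS, so recovery is immediate:

* **Emergency (h, g, l)** — an unplanned case of length class
  γ<sub>l</sub> ∈ {1 h, 2 h, 4 h} arrives at slot *h* of protected day *g*.
  It is inserted into the *first available* OR; electives on that OR may be
  displaced but must reappear within Δ = 7 days, with up to Ω = 1 h
  recovery overtime.
* **No-show (b, g)** — patient *b* scheduled on day *g* cancels. A
  pre-designated **substitute** from day *g+1* takes the freed slot (with
  overtime allowance) and *b* is rescheduled exactly Δ̂ = 2 days later.

Everything is one mixed-integer linear program. Scheduling patient *i* on
day *d* costs

&nbsp;&nbsp;&nbsp;&nbsp;p<sub>id</sub> = (d + max(m<sub>i</sub> + d − l<sub>i</sub>, 0)) · u<sub>i</sub>,&nbsp;&nbsp;&nbsp;&nbsp;u<sub>i</sub> = 360 / l<sub>i</sub>,

and leaving them off the plan costs
q<sub>i</sub> = (m<sub>i</sub> + |D| + 1 + max(m<sub>i</sub> + |D| + 1 − l<sub>i</sub>, 0)) · u<sub>i</sub> > p<sub>id</sub>,
so urgent and long-waiting patients are pulled forward and exclusion is
never cheaper than scheduling. The solution procedure is sequential:
nominal solve → a warm-start or minimize-difference (matheuristic) route to
a complete solution (NS + all RSs) → emergency-plan optimization (which
also fixes the within-day ordering) → no-show-plan optimization.

Every bundle is re-verified by an **arithmetic validator** that re-evaluates
all constraint blocks without trusting the solver, and a brute-force oracle
provides exact ground truth on tiny instances.

## Worked example

```r
library(surgsched)

inst <- generate_instance(generator_config(
  n_patients = 20, horizon_days = 14, num_ors = 2, mix = "A", seed = 1))
inst
#> <or_instance> 20 patients, 14 days x 2 ORs, RS days 1..1
#>   capacity 24-24 slots (15 min), overtime 4, delta 2/7, emergencies [4,8,16]

bundle <- full_pipeline(inst, solve_config("warm_start",
                                           time_limit = 60, gap = 0.05))
bundle
#> <schedule_bundle> 20 scheduled / 20 patients; 72 emergency + 20 no-show plans
#>   nominal    of=88         bound=88         status=optimal
#>   complete   of=88         bound=88         status=optimal
#>   emergency  of=93.01      bound=88.53      status=optimal_fixed_order+mu_repair
#>   noshow     of=1385       bound=1292       status=optimal

validate_bundle(bundle)
#> <violation_report> no violations

head(nominal_schedule(bundle), 3)
#>   patient day or position start_slot
#> 1    P001   1  1        1          1
#> 4    P010   1  1        2          3
#> 2    P003   1  1        3          5

substitutes(bundle)          # the pre-designated no-show cover, one per OR
#>   day or patient
#> 1   1  1    P004
#> 2   1  2    P020

# what actually happens if the first day-1 patient cancels:
apply_noshow(bundle, "P001", 1)[c("substitute", "or", "return_day")]
#> $substitute: "P004"   $or: 1   $return_day: 3

# ... or if a 4-hour emergency arrives 1h45 into day 1 (slot h = 7):
apply_emergency(bundle, h = 7, g = 1, l = 3)[c("or", "displaced",
                                               "elective_load", "load_bound")]
#> $or: 1   $displaced: "P005" "P007" "P011"
#> $elective_load: 12   $load_bound: 12     # 24 - min(16, 24-7) + 4

render_gantt(bundle, day = 1)
#> OR1 |[1[0[333[7777777[333[1..|
#> OR2 |[44[2[22[99[8888888[5[66|
#>      ------------------------
#>      slots 1..24 (15 min each)
```

Here `nominal of=88` is the optimal waiting-list penalty of the NS;
`complete of=88` means guaranteeing recoverability cost nothing on this
instance (the *price of robustness*, `OF_complete − OF_nominal`, is always
≥ 0 and is reported in the metrics CSV written by `write_metrics_csv()`).
The emergency/no-show objectives are scenario-averaged penalties of the
restoration plans: the 4-hour emergency at slot 7 is inserted into OR1
(the first to free up), exactly three electives starting after slot 7 are
displaced into later days, and the day-1 elective load lands precisely on
the reduced-capacity-plus-overtime bound.

A command-line interface covers the same flow
(`generate` / `solve` / `validate` / `report`); see `cli_main()` or the
installed `exec/surgsched` script.

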