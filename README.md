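# orsched

Operating-room surgery scheduling with metaheuristic solvers.

## The problem

Surgical waiting lists routinely outgrow the operating-room (OR) time
available to serve them. Each listed surgery carries an estimated duration,
a room-turnover time, the day the patient entered the list, an ordinal
priority level, and a *guaranteed maximum response time* — a regulatory
deadline by which the surgery should be performed. The bookable resource is
a set of **slots**: shifts of one OR on one day, each reserved for a single
specialty, with a capacity in minutes and an optional cap on the number of
surgeries it may host.

A schedule assigns surgeries to slots (possibly leaving some unscheduled
when nothing can take them). Its quality is the **penalty score**

```
pt = Σᵢ pᵢ ,   pᵢ = max(0, dᵢ − dsᵢ) · w(prᵢ)
```

where `dᵢ` is the day surgery *i* is scheduled on, `dsᵢ` its deadline day,
and `w(prᵢ)` the weight of its priority level (defaults 1, 2, 4, 8 for
levels 1–4). On-time and unscheduled surgeries contribute zero; unscheduled
cases are reported in their own column, and the solvers additionally charge
a configurable per-unscheduled cost in the objective they minimize so that
scheduling a surgery — even late — always beats dropping it.

`orsched` is aimed at health-systems operations researchers and hospital
planners who want to benchmark scheduling heuristics on realistic,
fully synthetic workloads. It provides:

* domain objects with structural validation (`ssp_instance`,
  `ssp_schedule`, `validate_instance`, `check_feasibility`);
* the penalty objective and schedule metrics (`total_penalty`,
  `schedule_delta`, `compare_report`);
* an initial-solution constructor: waiting list ordered by priority, then
  waiting-list longevity (`order_waiting_list`), packed by first fit
  (`first_fit_assign`);
* three solvers sharing one swap/relocate neighbourhood: hill climbing
  (`hill_climb`), simulated annealing (`simulated_annealing`) and a
  canonical global-best particle swarm over an encoded slot-index space
  (`particle_swarm`);
* a synthetic workload generator (`generate_instance`) emulating an
  overloaded three-specialty surgical centre (198/133/98 surgeries against
  122/89/45 slots), a planted-feasible mode with a certified zero-penalty
  optimum (`generate_planted_instance`), and a manual-scheduling baseline
  emulator (`generate_manual_baseline`);
* CSV/YAML readers and writers plus a command-line interface
  (`inst/cli/orsched.R`: `generate`, `solve`, `evaluate`, `compare`).

## Worked example

Build a planted-feasible instance of 100 surgeries in 40 shifts (so a
zero-penalty schedule is known to exist), construct the first-fit initial
solution, and optimize it with hill climbing:

```r
library(orsched)

spec <- generator_spec(specialties = "general", n_surgeries = 100L,
                       n_slots = 40L, horizon_days = 40L)
gen <- generate_planted_instance(spec, seed = 7)
instance <- gen$instance

init <- first_fit_assign(instance)
total_penalty(init, instance)
#> penalty score (pt): 219
#>   without penalty: 71   with penalty: 29   unscheduled: 0

res <- hill_climb(instance, init, solver_control(max_iters = 500, seed = 7))
res
#> hc solver result: penalty score 0 (objective 0)
#>   stabilized after 5 sweep-iteration(s) of 500
#> ssp_schedule: 100/100 surgeries scheduled (0 unscheduled)
```

The first-fit start is already feasible but books 29 surgeries past their
deadlines (score 219); hill climbing repairs all of them within a few
sweeps, reaching the certified optimum of 0. Comparing against an emulated
manual baseline (entry-date-only ordering plus random displacements):

```r
baseline <- generate_manual_baseline(instance, disruption = 0.3, seed = 7)
compare_report(baseline, list(hc = res$best_schedule), instance)
#> specialty  schedule   penalty   without pen.   with pen.   unscheduled
#> general    baseline      1195      64 (64.0)   36 (36.0)       0 (0.0)
#> general    hc               0    100 (100.0)     0 (0.0)       0 (0.0)

schedule_delta(res$best_schedule, baseline, instance)
#> schedule delta over 100 surgeries scheduled in both:
#>   earlier in a: 51   same day: 2   later in a: 47   mean shift: -2.53
```

The report mirrors the per-specialty metric table (penalty score; n (%)
without penalty, with penalty, unscheduled), and the delta summary shows
the optimized plan books surgeries 2.5 days earlier on average.

The same run from a shell:

```sh
Rscript inst/cli/orsched.R generate --out-dir data --seed 7 --planted \
    --n-surgeries 100 --n-slots 40 --horizon 40
Rscript inst/cli/orsched.R solve --instance data/instance.yaml \
    --algorithm hc --iters 500 --seed 7 --out data/hc.csv --trace data/trace.csv
```

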