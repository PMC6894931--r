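# multipatch

Tools for planning, simulating and analysing **multineuron patch-clamp
(multipatch) experiments** that map synaptic connectivity in brain slices.

Multipatch rigs record from up to ten neurons at once and probe every
ordered (pre, post) pair for a synaptic connection: four action potentials
at 20 Hz are evoked in each cell in turn while the other cells are watched
for postsynaptic potentials in sweep-averaged traces. With `n` cells held
simultaneously, `c = n(n−1)` directed connections are testable, and
pipette *cleaning* extends this: failed pipettes are cleaned and retried
until the cluster is full (*clean-to-complete*), or, after a full
recording, some pipettes move on to fresh cells while others keep theirs
(*clean-to-extend*), adding

```
c_new = 2·n_new·n_old + n_new·(n_new − 1)
```

newly testable pairs per session. The package is aimed at people building
or simulating such rigs and at analysts who want a fully testable,
ground-truth-driven implementation of the standard multipatch analysis
chain. It provides:

* **planner** — session combinatorics (`pairsTotal`, `pairsExtension`,
  `planSummary`), success-rate arithmetic and a stochastic yield model;
* **rig geometry** — Kabsch registration between manipulator and
  microscope frames, staging-target planning, axis-aligned approach paths,
  wall-clearance reachability;
* **pressure rig** — a virtual pneumatic controller: channel/valve-tree
  routing, the patching-phase state machine, and the timed
  suction/expulsion cleaning schedule (5 × (−350 mbar 1 s, +1 bar 1 s),
  then two 10 s expulsions);
* **synthgen** — a seeded generator of synthetic recordings (test pulses,
  AP trains with analytic threshold/half-width ground truth, spontaneous
  EPSP traces, and full multi-cell sweep sets with known connectivity);
* **ephys features** — resting potential, access/input resistance from a
  200 ms/10 mV test pulse, spike detection, the 10 mV/ms threshold rule,
  rheobase stimulus selection, and quality-control filters (RMP more
  positive than −60 mV or access resistance ≥ 40 MΩ excluded);
* **psp detect** — Clements–Bekkers template-scaling detection of
  spontaneous EPSPs and evoked-connection calling on averaged sweeps;
* **constats** — connection probability, Fisher's exact test, the Wald
  interval for a difference of proportions, TOST equivalence reports on
  relative differences, rank tests and distance summaries;
* **io** — a plain-text sweep container with bit-exact round trips, graph
  exports (edge CSV / adjacency JSON / GraphML), and a one-call pipeline
  (`runPipeline`) plus a CLI (`exec/mpk`).

## Worked example

Accounting for a three-session clean-to-extend experiment — eight cells
patched simultaneously, then 4 new/4 maintained, then 5 new/3 maintained:

```r
library(multipatch)

plan <- SessionPlan(list(c(8, 0), c(4, 4), c(5, 3)), nPipettes = 8)
ps <- planSummary(plan)
ps$per_session
#>   n_new n_old tested
#> 1     8     0     56
#> 2     4     4     44
#> 3     5     3     50
c(ps$total_cells, ps$total_tested)
#> [1]  17 150
```

150 tested directed connections between 17 neurons from one slice — the
first cluster contributes 8·7 = 56, the extensions 44 and 50.

Generate a synthetic 8-cell cluster with known connectivity, screen every
ordered pair, and compare against the ground truth:

```r
ss <- synthCluster(8, p_conn = 0.15, n_sweeps = 40, seed = 42)
ss
#> SweepSet: 8 cells x 40 sweeps, 70000 samples @ 20 kHz
#>   ground truth: 10 true edges

calls <- detectConnections(ss, k_sd = 10)
sum(calls$connected)
#> [1] 10                     # exactly the 10 true edges, no false calls
connectionProbability(sum(calls$connected), nrow(calls))
#> [1] 0.1785714
```

`k_sd = 10` is the recommended screening threshold (the vignette derives
it from the separation between noise extrema and the smallest detectable
unitary PSP). Comparing two connectivity datasets:

```r
w <- waldCiDiff(38, 150, 20, 150)       # found/tested in two conditions
w$diff; w$ci
#> [1] 0.12
#> [1] 0.04586 0.19414                   # 90% Wald CI, no continuity corr.
fisherExact(38, 150, 20, 150)
#> [1] 0.01249
```

The same steps run from the shell:

```sh
mpk plan summary plan.json
mpk synth cluster --cells 8 --p-conn 0.15 --sweeps 40 --seed 42 -o cluster
mpk connect detect cluster -o edges.csv --k-sd 10
```

## Further reading

The methods vignette (`vignettes/multipatch-methods.Rmd`) documents the
models and their assumptions: the session-plan invariants, the yield
model, the valve-tree bijection, the analytic AP/PSP ground truths and the
noise convention, every detection threshold and why the screening
threshold differs from the single-pair default, the statistics, and the
known limitations.
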