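# moveonset

Mechanisms of collective movement onset: did the group **vote, then
move**, or did individuals **copy** each other as they left?

`moveonset` is for movement ecologists working with per-individual 1 Hz
tracking data (GPS position plus body heading, e.g. from
magnetometer-equipped collars) on small animal groups.  It couples an
agent-based simulator of collective departures with the complete analysis
pipeline that discriminates decision mechanisms from trajectory data.

## The statistic at the core

For a group with mean heading α₁ and departure direction α₂, the
*decision parameter*

    r = || ( (cos α₁ + cos α₂)/2 , (sin α₁ + sin α₂)/2 ) || = |cos((α₁ − α₂)/2)|

runs from 0 (group pointing away from the departure direction) to 1
(pointing at it).  Around each detected departure, r(t) is
cross-correlated with the group mean speed; the lag of maximal
correlation (**CorrMax**) and the left/right asymmetry of the
cross-correlation curve (**Sym**) are pooled over events as medians with
bootstrap 95% CIs.

* Voting ("point, then move") ⇒ orientation consensus precedes
  acceleration ⇒ CorrMax and Sym negative.
* Copying ⇒ consensus concurrent with acceleration ⇒ both ≈ 0.

The verdict rule is a pure function of the CIs: *copying-consistent* iff
both CIs contain 0; *vote-consistent* iff the CorrMax CI is entirely
negative; otherwise *indeterminate*.

The package also provides: change-point based departure detection (exact
penalized segmentation with penalty-sensitivity sweeps), polar order,
departure/destination directions, a pre-departure alignment t-test
against the chance level 2/π, and leader–follower network statistics
(pairwise time-lag heading correlations, normalized David's score,
triangle transitivity, directional consistency, permutation p-values).

## Worked example

Simulate one day of eight collective departures under the all-vote
mechanism, then run the full pipeline on the resulting trajectory table:

```r
library(moveonset)

ds     <- simulate_dataset(agent_config(mechanism = "all_vote"),
                           n_events = 8, seed = 501)
report <- run_pipeline(ds$table, run_config(rng_seed = 11, bootstrap_n = 500),
                       leadership = FALSE)
print(report)
#> Collective-departure pipeline report
#>   seed:             11
#>   candidate events: 8
#>   retained events:  6
#>   CorrMax median:  -23.0 s  [-23.0; -21.0]
#>   Sym median:      -4.82  [-5.12; -3.97]
#>   pre-departure r: 0.50 (t = -0.79, df = 5, p = 0.463)
#>   verdict:          vote-consistent
```

Reading it: of 8 candidate departures, 6 survive the exclusion filters
(first and last of the day are dropped as possibly observer-influenced).
The decision-parameter/speed cross-correlation peaks at −23 s — the
groups aligned on the departure direction tens of seconds *before*
speeding up — and the symmetry index CI is entirely negative, so the
verdict is *vote-consistent*, matching the generating mechanism.  The
pre-departure r at −100 s is at chance (0.50 ≈ 2/π ≈ 0.64 is not
rejected) because −100 s predates the vote itself.

Model predictions for a dataset of 21 decisions under copying (the
scaled analogue of the prediction-statistics procedure):

```r
p <- simulate_predictions(agent_config("copying"), n_events = 50,
                          n_resample = 200, seed = 7)
#> copying predictions: CorrMax 0.02 [0.00; 0.00], Sym -0.73 [-1.82; 1.61]
```

Both prediction intervals contain 0: copying produces no anticipatory
signature.

A command-line interface covers the same workflow
(`exec/moveonset`, verbs `simulate`, `detect`, `report`/`all`,
`predict`; `--sensitivity` adds a change-point penalty sweep).

## Layout

* `R/trajectories.R` — trajectory table, CSV I/O, configuration.
* `R/kinematics.R`, `R/angles.R` — speeds, circular statistics, polar order.
* `R/changepoints.R` — penalized exact segmentation (PELT-style).
* `R/decisions.R` — departure detection, exclusion filters, directions.
* `R/metrics.R` — decision parameter, cross-correlation, CorrMax/Sym,
  bootstrap, t-test.
* `R/agents.R` — the departure simulator (copying / all-vote / sub-vote),
  day-level dataset generator, sensor noise, cohesion metrics.
* `R/leadership.R` — dyad scoring, leadership matrix, normDS, t_tri, dc.
* `R/pipeline.R`, `R/cli.R` — orchestration, verdict, CLI.

The methods vignette (`vignettes/moveonset-methods.Rmd`) documents the
model, the detection and statistical choices, and known limitations —
including one deliberately unresolved red test (end-to-end categorical
recovery of copying), whose cause is analysed there.
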