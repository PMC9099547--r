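# frailtykit

Ambient-sensor frailty indicators and their concurrent validation, for
researchers building in-home frailty monitoring from non-wearable,
non-camera sensors in a single-occupant dwelling.

A pressure mat, paired ultrasonic distance sensors on a staircase, one PIR
motion sensor per room, a door contact, a smart weight scale and a smart
speaker each map onto a Fried-phenotype criterion (strength via sedentary
behaviour and stair performance, exhaustion via self-report, physical
activity, shrinking, life-space mobility).  `frailtykit` turns the raw
timestamped event streams into the corresponding indicators — each one a
plain subtraction of two event times —

- sedentary duration `s = t_unoccupied − t_pre_occupied`
- stair-climbing time `sc = |t_distance2 − t_distance1|`
- room-presence duration `r = t_next_motion − t_pre_motion`
- outing `o = 1` iff `od = t_door − t_pre_door > 5 min` with no interior
  sensor event

— aggregates per-criterion flags into a frailty state (0 positives =
non-frail, 1–2 = pre-frail, 3–5 = frail), and quantifies agreement with
ground truth via Cohen's kappa `k = (p_o − p_e)/(1 − p_e)`, Bland–Altman
limits of agreement `bias ± 1.96·sd` (no agreement if > 20% of pairs fall
outside), detection rates, and Pearson correlation.  A built-in HomeLab
simulator replays the three-run test protocol through per-sensor
observation models so the whole pipeline runs with no external data.

## Worked example

```r
library(frailtykit)

truth <- generate_session(seed = 42)          # ground-truth protocol session
log   <- observe(truth, sensor_model(), seed = 43)  # corrupt into events
ind   <- derive_indicators(log)
ind
#> <indicator_set> 3 sedentary bouts, 2 stair climbs, 19 room presences,
#>   2 confirmed outings / 4 spans, 3 weight readings, 9 dialogue answers
head(ind$bouts, 3)
#>        t_pre_occupied        t_unoccupied       s complete
#> 1 2021-06-01 09:04:13 2021-06-01 09:05:42  88.408     TRUE
#> 2 2021-06-01 09:30:23 2021-06-01 09:31:53  90.542     TRUE
#> 3 2021-06-01 09:54:21 2021-06-01 09:57:30 189.658     TRUE
```

Three sitting bouts survived the pressure-mat observation model (durations
in seconds); only 2 of 6 stair climbs were detected because the default
sensor model reproduces the 50% out-of-range miss rate observed for the
distance sensors, and 2 absences exceeded five minutes with no interior
events, so they count as confirmed outings.

The full nine-participant validation study, one report block per sensor:

```r
run_validation_study(9, seed = 1)
#> Simulated concurrent-validity report (9 participants, 324 activities, seed 1)
#>   speaker : 100.0% token agreement (n = 81)
#>   motion  : kappa = 1.000 (p_o = 1.0000, p_e = 0.2140, p < 0.001)
#>   door    : 94.4% detected (51/54)
#>   mat     : 100.0% detected; bias = 0.000, sd = 0.000, LoA = (0.000, 0.000), 0.0% outside -> agreement
#>   distance: 44.4% detected; bias = 0.000, sd = 0.000, LoA = (0.000, 0.000), 0.0% outside -> agreement
#>   weight  : r = 0.999 (n = 27)
```

Timestamp noise is zero by default, so duration agreement is exact (bias
and SD both 0) while the door and distance detection rates hover around
their configured 87.5% and 50% targets.  The published kappa worked
example reproduces directly:

```r
round(cohens_kappa_from_proportions(0.9558, 0.2882)$k, 3)
#> [1] 0.938
```

## Command line

```sh
Rscript inst/cli/frailtykit simulate --seed 5 --out-dir out
Rscript inst/cli/frailtykit derive   --out-dir out
Rscript inst/cli/frailtykit report   --seed 5 --out-dir out
Rscript inst/cli/frailtykit show-config
```

All parameters (debounce, pairing window, outing threshold, agreement
grid, simulator noise) live in one YAML config; `show-config` prints the
documented defaults.

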