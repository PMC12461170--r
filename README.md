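# shadowzone

Quantify how much of a hospital unit goes *unwatched* — and whether that
matters for patient safety — from real-time location system (RTLS)
trajectories of mobile workstations (nursing carts).

Hospital falls are a persistent safety problem, and caregiver visibility
is one of the few modifiable environmental factors. When carts carry
ultrawideband RTLS tags, their movement traces where caregivers have
recently been. `shadowzone` turns raw tag position streams into a
per-minute **percentage of spatial shadow zone** and relates it to fall
and ICU-transfer events. It is written for clinical-informatics and
patient-safety researchers working with indoor-positioning exports.

## The statistic

The unit is partitioned into a grid of 1 m × 1 m cells. Each minute,
every present workstation covers the cell it occupies plus a Chebyshev
dilation of *d* cells in all cardinal and diagonal directions (a
(2*d*+1) × (2*d*+1) block; *d* = 2 m by default, the personal/social zone
of proxemics theory). A cell is a **spatial shadow zone** at minute *t*
when it has been outside every workstation's coverage for at least *T*
consecutive minutes ending at *t* (*T* = 60 min by default, the
conventional rounding interval). The per-minute statistic is

```
percent_shadow(t) = 100 · |{cells uncovered for ≥ T consecutive minutes}| / |unit cells|
```

Minute-level association analysis follows: Welch *t* contrasts of shadow
percentage between event-exposed and unexposed minutes, and multivariable
logistic regression of per-minute event flags on shadow percentage
adjusted for patient-to-nurse ratio and day of week, with sensitivity
grids over *d* ∈ 1–4 m and *T* ∈ 15–90 min and a temporal split-half.

The package also ships trajectory quality control (the isolated-jump
noise rule at 2.5 m, hourly missing-rate metrics for the 1 Hz-moving /
1-per-minute-stationary emission regime), positional-accuracy validation
against a ground-truth route (error CDF and quantiles), and a seeded
synthetic-data generator that emulates cart movement, emission regimes,
positioning artifacts and event processes — so the entire pipeline runs
and is testable without access to clinical data.

## Worked example

A two-week synthetic study, run through the full pipeline:

```r
library(shadowzone)

cfg <- sim_config(seed = 11, days = 14, target_falls = 25, target_icu = 12)
sim <- simulate_study(cfg)
sim
#> <sim_study> 14 day(s), 4 workstation(s), 40 bed(s)
#>   139854 emissions (117825 after corruption), 25 fall(s), 5 ICU transfer(s)

qc <- filter_noise(sim$stream)            # isolated jumps > 2.5 m removed
quality_report(qc$report)
#> <quality_report>
#>   points: 117825, noise: 460 (0.390%, 1 in 256)

frames <- resample_per_minute(qc$stream, sim$grid,
                              start = cfg$start, end = cfg$start + 14 * 86400)
series <- shadow_series(frames, shadow_params(d_cells = 2, T_minutes = 60))
series
#> <shadow_series> 20160 minutes, d = 2 cell(s), T = 60 min
#>   percent shadow: mean 57.2, range 0.0--85.0

tab <- label_minutes(series, sim$events)  # 60-min exposure windows
compare_groups(tab, "fall")
#> <shadow_comparison> fall minutes
#>   event:     mean 59.9 (SD 7.4), n = 1397
#>   non-event: mean 57.0 (SD 8.5), n = 18763
#>   difference 2.90 pp (95% CI 2.50 to 3.31), p = 1.55e-42

fit_event_model(tab, "fall")
#> <shadow_glm> logistic model of fall minutes (n = 20160)
#>     term odds_ratio               ci       p
#>  percent      1.051 (1.043 to 1.059) < 2e-16
#>    ratio      0.870 (0.833 to 0.909) 5.9e-10
#>  ...
```

Reading the numbers: on average 57% of the unit had not seen a cart
within the trailing hour; minutes in the hour before a fall carried about
2.9 percentage points more shadow than other minutes; and each additional
percentage point of shadow multiplied the per-minute odds of a fall by
1.051 (after adjustment for staffing ratio and weekday). The noise rate
exceeds the injected 0.226% because deletions in the 1 Hz regime can make
genuine consecutive observations jump farther than 2.5 m — see the
methods vignette (`vignettes/shadow-zone-methods.Rmd`).

Real exports enter through `read_positions()`, `read_events()`,
`read_route()` and `read_shift_schedule()` (CSV; ISO-8601 timestamps). A
thin command-line front end with `simulate` / `shadow` / `validate` /
`associate` subcommands is installed under `exec/`.

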