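---
title: "Quantifying spatial shadow zones from RTLS trajectories: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial shadow zones from RTLS trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the statistic

Caregiver visibility is a recognized environmental factor in hospital fall
risk, but it is usually assessed by manual observation. When a unit's
mobile workstations (nursing carts) carry real-time location system (RTLS)
tags, their trajectories give a continuous, objective proxy for where
caregivers have recently been — and, by complement, where they have not.

`shadowzone` turns raw tag position streams into a per-minute **percentage
of spatial shadow zone**. The unit floor plan is partitioned into square
grid cells (1 m by 1 m by default). Each minute, every present workstation
covers the cell it occupies plus a *Chebyshev dilation* of `d` cells in all
cardinal and diagonal directions — a `(2d+1) x (2d+1)` block approximating
the visual and functional range of a caregiver near the cart (`d = 2` m by
default, consistent with the personal/social zone of proxemics theory). A
cell is a *shadow zone* at minute `t` when it has been outside every
workstation's coverage for at least `T` consecutive minutes ending at `t`
(`T = 60` min by default, the conventional rounding interval). The
statistic is

    percent_shadow(t) = 100 * (# shadow cells at t) / (# unit cells),

i.e. shadow area over total unit area (400 m² at the default 20 m x 20 m
geometry). The per-minute series is then related to fall and
intensive-care-transfer events through minute-level group contrasts and
adjusted logistic regression.

## From emissions to minutes

Tags emit at 1 Hz while the cart moves and once per minute when it is
stationary (a battery-saving regime). The pipeline therefore:

1. **Noise-filters** the stream: a record is a spurious displacement iff
   its planar distance to *both* the preceding and following emission of
   the same tag exceeds 2.5 m. A point far from only one neighbour is a
   legitimate move; two consecutive displaced points are a sustained
   excursion, not noise. First/last records of a tag are never flagged.
   The filter is idempotent on realistic trajectories.
2. **Resamples to calendar minutes**: a tag's position at a minute is its
   last emission at or before the minute's end, carried forward while at
   most `max_staleness = 2` minutes old. That tolerates one missed
   stationary beacon; longer silence makes the tag absent, contributing no
   coverage. No carry-forward rule is inherent to the statistic, so the
   limit is a parameter.
3. **Tracks uncovered runs incrementally**: one integer counter per cell,
   reset to zero on coverage and incremented otherwise; the shadow mask is
   `counter >= T`. This is algebraically identical to scanning the last
   `T` coverage rasters each minute, and the test suite checks bitwise
   equality against exactly that sliding-window recomputation on
   randomized instances. Minutes with no present tags still advance every
   counter — absence is precisely what the statistic measures.

Counters start at zero at stream start (cells presumed recently visited).
The first `T` minutes therefore cannot contain a full uncovered run that
began before observation; `warmup = "mask_first_T"` masks them for users
who prefer to drop that ramp-in. The height coordinate, when present, is
read and ignored: the analysis is planar and the unit single-storey.

## Quality metrics

Two stream-quality metrics accompany the filter. The *noise rate* is
`flagged / total`, also reported in "1 in k" form (`round(total/flagged)`).
The *hourly missing rate* needs an expectation model, because the expected
emission count depends on the motion regime and no formula is inherent in
the regime description. The package classifies each inter-emission gap as
stationary when its duration falls in [45, 75] s (the once-per-minute
cadence with tolerance) **or** the displacement across it is under 0.5 m;
expected emissions over a gap of `g` seconds are then `g/60` (stationary)
or `g` (motion at 1 Hz). Gaps attribute to the clock hour of their ending
emission, and the per-hour rate is `1 - observed/expected`, clipped to
[0, 1]. Under this model a complete once-per-minute stream scores 0 —
the stationary beacon-rate reduction is excluded from the 1 Hz
expectation. This is one defensible reading among several; both window and
displacement thresholds are arguments.

## Accuracy validation

Positional accuracy is scored against a ground-truth route: each estimate's
error is its minimum Euclidean distance to the route polyline, with
projections clamped to segment endpoints. No time alignment is attempted
because validation routes record no per-point timestamps; nearest-point
distance is the operational definition. Summaries are the mean, sample SD,
a normal-approximation 95% CI of the mean, empirical quantiles (type 7,
linear interpolation between order statistics — stated because
80th-percentile figures depend on the convention), and the empirical CDF.

One numerical subtlety informs the validation tests: distance to a
polyline discards the error component tangential to the route, so the
isotropic-Gaussian closed form for the mean 2D error, `sigma*sqrt(pi/2)`
(the Rayleigh mean), applies only when the reference is point-like. The
Rayleigh cross-check therefore uses a degenerate route — two vertices 1 mm
apart, a marked stationary station — for which polyline distance equals
the full Euclidean error. Against an extended route the expected mean
error is smaller (approaching the half-normal mean `sigma*sqrt(2/pi)` for
long straight segments).

## Association analysis

The unit of analysis is the calendar minute. A minute is event-exposed iff
it lies in the window of `window_minutes` ending at (and including) the
event's minute; windows of nearby events merge and are truncated at the
series start. The default window equals `T` (60 min): the shadow value at
the event minute already summarizes the preceding hour, and an hour of
exposed minutes per event matches the scale at which minute-level unit
studies tabulate event minutes. The window is a parameter, not a derived
quantity, because no window rule is forced by the statistic.

Group contrasts use the Welch unequal-variance two-sample t test
(two-tailed): exposed and unexposed minute groups differ enormously in
size and need not share a variance. The regression is a multivariable
logistic model of the per-minute flag on the shadow percentage, adjusted
for the patient-to-nurse ratio of the shift in force (day 7:1, evening
9:1, night 10:1 by default) and day-of-week dummies with Monday reference;
odds ratios are per percentage point and per patient-per-nurse, with Wald
95% CIs and no multiplicity correction. With a handful of events over a
long study, some weekday routinely has zero exposed minutes; its dummy is
then quasi-separated while the exposure coefficient remains identifiable,
so the fit reports such levels with a message and errors only on perfect
separation (an exactly predicted outcome or a diverging continuous
coefficient). `adjust = FALSE` fits the exposure-only model, the matched
design for parameter-recovery experiments against the generator.

The sensitivity grid recomputes the series and the group contrast for
every dilation in 1–4 cells and threshold in 15–90 min, relabeling with
`window = T` per cell; a single counter pass per dilation serves all
thresholds, since uncovered-run lengths do not depend on `T`. The
split-half analysis cuts the minute table at the midpoint week boundary
and reruns the contrast per half. The unit fall rate is
`1000 * falls / (beds * days)` per 1000 patient-days.

## The synthetic generator

No public RTLS dataset of this kind exists, so the generator is
first-class: it emulates the data-generating process well enough to
exercise and score every stage.

* **Movement**: each workstation is a bed-to-bed semi-Markov process —
  lognormal bedside dwells (median 20 min, sdlog 0.6; carts are parked
  most of the time and make occasional rounds) alternating with
  straight-line transits at U(0.5, 1) m/s among 40 beds lining the two
  long walls of a 20 m x 20 m unit. Dwells beacon once per minute,
  transits emit at 1 Hz. The dwell distribution is a convention chosen for
  realism (no distributional facts about real cart dwells are available)
  and is configurable.
* **Corruption**: isolated jumps displace a point by U(4, 8) m at rate
  0.226%; the lower bound clears the 2.5 m isolation rule even next to
  1 m transit steps, so every injected artifact is detectable in
  principle. Candidates adjacent to another candidate or at a tag's
  first/last record are skipped. Motion-regime emissions are independently
  deleted at rate 0.376 (the stationary beacons are left intact — the
  missing-rate figure this emulates describes the 1 Hz regime after
  excluding tag-inactivity reductions).
* **Events**: per-minute Bernoulli draws with
  `logit p = b0 + beta * percent_shadow`, `beta = ln(1.02)` for falls and
  `ln(0.99)` for ICU transfers; `b0` is calibrated by root finding so the
  expected counts match the study scale (8 falls and 89 transfers per 210
  days, scaled by simulated span). Generation is two-pass: transfers are
  drawn first, then a response cart ("W0") beacons at the event bed for
  the 60 minutes before each transfer — intensified bedside activity
  preceding deterioration — and the shadow series is recomputed before
  falls are drawn. This clustering is the mechanism that produces the
  inverse shadow–ICU association.
* **Reproducibility**: one seed; each phase (trajectories, corruption,
  transfers, clustering, falls) draws from its own derived substream, so
  toggling one leaves the others bit-identical.

What the generator does **not** emulate: walls and line-of-sight occlusion
(coverage is purely metric, as in the statistic's definition), multi-floor
units, correlated or bursty data loss, heterogeneous per-tag accuracy, and
any behavioural realism beyond the dwell/transit alternation. Passing
recovery tests therefore demonstrates that the pipeline measures what the
generative model encodes — not that real wards satisfy that model.

## Problem sizes and numerical conventions

The test suite exercises: oracle equivalence on 100 randomized grids (up
to 10 x 10 cells, up to 300 minutes); monotonicity of the full 4 x 6
sensitivity surface on one simulated day; parameter recovery over 200
replicates of 7 simulated days with the baseline fall rate inflated to
about 200 events per replicate for power (recovery labels the event
minute only and fits the matched unadjusted model — with a 60-minute
exposure window the fitted per-minute odds ratio deliberately absorbs the
window autocorrelation and sits above the generating value); one
full-scale 210-day study for direction-of-effect; and quality-control
recovery on about one million emissions from a transit-heavy fleet. These
sizes keep the whole suite in the minutes range on a single core while
leaving every estimate comfortably inside its Monte-Carlo tolerance.

Conventions worth stating: cells are half-open `[k, k+1)` intervals
indexed from the boundary bounding-box minimum, so a position exactly on
an interior cell edge belongs to the higher-index cell; positions outside
the unit polygon occupy no cell and contribute no coverage; duplicate
`(tag, time)` rows keep the first occurrence; timestamps are normalized to
UTC; a meter-specified dilation maps to `round(d_m / cell_size)` cells.
Ties in the event-window union are immaterial because windows merge by
set union.

## Limitations

Shadow percentage is a proxy for visibility, not a measurement of it:
obstructions, task context and gaze are invisible to an RTLS. The
association models treat minutes as independent, which understates
uncertainty under strong autocorrelation of the shadow series — the same
limitation the minute-level design has on real data. The generator's event
processes are conditionally independent given the series, so recovered
coefficients validate the estimation machinery, not causal claims. And the
warm-up convention (counters start at zero) slightly undercounts shadow in
the first `T` minutes of any stream; mask them when that matters.
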