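---
title: "Evaluating 24-hour movement behaviour measures: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating 24-hour movement behaviour measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timeuse24)
```

## Scope

`timeuse24` implements the measurement-evaluation computations used when a
time-use questionnaire is validated against a thigh-worn
accelerometer/inclinometer: scoring questionnaire items into a closed 24-h
composition of sleep, sedentary behaviour (SB), light physical activity
(LPA) and moderate-to-vigorous physical activity (MVPA); processing device
event streams together with sleep diaries into daily and weekly behaviour
estimates; and the reliability/validity statistics battery (two-way mixed
intraclass correlations, bootstrap Spearman correlations, Bland–Altman
agreement, Bonett sample-size planning). Because raw data from such studies
are rarely deposited, the package carries a first-class synthetic-data
generator: cohorts with *known* latent compositions, so that every stage of
the pipeline can be verified against ground truth rather than against
irreproducible numbers.

## The composition model

A day has 1440 minutes, so the four behaviour durations are co-dependent:
any valid estimate must satisfy

$$\text{sleep} + \text{SB} + \text{LPA} + \text{MVPA} = 1440\ \text{min}.$$

Both measurement arms enforce closure by construction: LPA is always the
24-h remainder after sleep, SB and MVPA. Records whose remainder is
negative (over-reporting) are *flagged invalid rather than truncated* —
truncation would hide exactly the closure failures a validation analysis
needs to see.

## Questionnaire scoring

Scoring follows the instrument's processing rules:

* **Sleep** = time in bed (bed time → rise time, wrapping over midnight;
  a rise time at or before bed time means next-day rise) − sleep latency −
  wake after sleep onset + (nap days × nap duration)/7.
* **SB** = occupational + commuting + other non-occupational sitting.
  Occupational sitting is workplace span × a visual-analogue proportion ×
  workdays/7. Commuting and "other" items are treated as already-daily
  averages — the instrument's distributed spreadsheet is not public, so the
  day-weighting of those two domains is a documented convention of this
  package, kept configurable at the item-schema level.
* **MVPA** = occupational (gated by a yes/no item) + commuting + other,
  with day-counted domains averaged by days × duration / 7.

The item schema is the minimal closure of the quantities the scoring rules
require, published as a column dictionary (`dabq_response_columns()`), so a
full instrument export can be mapped onto it.

## Device processing

Days run **noon to noon** so that one night's sleep belongs to one
monitoring day. Per day:

1. **Candidate time in bed**: the longest run of sitting/lying events
   mergeable across interruptions totalling ≤ 15 min (bathroom breaks),
   ties broken by earliest start.
2. **Sleep onset fusion**: the diary bed time stands unless a burst of
   upright events occurs in the following 20 min, in which case onset moves
   to the first sitting/lying event after the last such burst.
3. **Sleep offset fusion**: the morning rise is the first upright burst
   after onset that (a) follows more than one hour of sitting/lying and
   (b) is not itself followed by more than an hour of renewed sitting/lying
   before the next burst. The diary wake time stands when it precedes that
   burst; otherwise the offset is the end of the last sitting/lying event
   before it. Requirement (b) is this package's disambiguation: without it,
   a 3-minute night-time bathroom break — which follows hours of lying and
   exceeds any sensible burst threshold — would terminate the sleep window
   in the small hours, which is plainly not what a combined diary/device
   protocol intends. With it, the rule reproduces all hand-traceable cases
   (burst inside/outside the look-ahead window, diary before/after the
   morning rise, missing diary) while keeping night interruptions inert.
4. **Waking classification**: sitting/lying → SB; stepping at or above a
   cadence cut-point (default 100 steps/min ≈ 3 METs; the published
   cadence→MET equation can be slotted in via `activpal_config()`) → MVPA;
   standing and slower stepping → LPA. Gaps in the event stream are
   non-wear. Events straddling a boundary are split.
5. **Naps**: diary nap minutes move from SB to sleep (they appear as
   daytime sitting in the events). If a nap exceeds the day's SB, only what
   exists is transferred and the day is flagged — the protocol literature
   is silent here, and clamping with a flag keeps totals closed without
   inventing sitting time.
6. **Non-wear**: a valid day has strictly more than 20 h of wear (≤ 4 h
   non-wear). Non-wear is reallocated proportionally to the three waking
   behaviours only; sleep is untouched; the day then closes to 1440 min.
7. **Weekly averaging**: arithmetic mean over valid days; participants with
   fewer than 5 valid days are excluded.

A "burst of upright events" is nowhere defined in the protocol literature;
here it is ≥ 1 min of cumulative standing/stepping within any 5-min span
(both numbers are configuration keys). This separates genuine rising from
isolated posture flickers of a few seconds.

## The statistics battery

With two measurements per participant (test/retest, or
questionnaire/device), the participants × measurements table yields the
two-way mean squares $MS_R$, $MS_C$, $MS_E$ and, with $k = 2$,

$$\mathrm{ICC}(C,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E}, \qquad
\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}.$$

Confidence intervals follow the single-measure two-way conventions of
McGraw & Wong (1996): exact F bounds for consistency, a Satterthwaite
approximation for absolute agreement. The test suite checks the point
estimates against an independent `aov()`-based oracle to 1e-10 and the
consistency interval's empirical coverage against its nominal 95%.

Spearman's ρ uses mid-ranks; its interval is a percentile bootstrap over
paired case resamples (B = 2000 by default; the protocol papers do not
state B or the interval type, so both are explicit arguments and a seed is
mandatory). Bland–Altman limits of agreement are mean ± 1.96 SD of the
differences, with t-based intervals using SE(LoA) = SD·√(3/n); the mean
difference carries a t-based interval (a normal-based one differs
negligibly at n > 100, but the t choice is explicit). Proportional bias is
the OLS slope of differences on pair means — the standard Bland–Altman
regression, stated here as an assumption because validation reports often
print β without defining the regression.

Bonett's closed-form planning formula gives the minimum n for a CI of
chosen width around an anticipated ICC; with ρ₀ = 0.70, half-width 0.10 and
k = 2 it returns n = 101, the classical "at least 100 participants" rule
for questionnaire validation studies.

## What the generator emulates — and what it does not

`cohort_config()` defines the study conditions. Defaults describe a
working-adult cohort of 126 with two questionnaire occasions seven days
apart and seven days of continuous device wear:

* **Latent compositions.** Sleep and SB are normal; MVPA is lognormal
  (strictly positive and right-skewed, as real MVPA distributions are),
  with SDs specified in minutes and converted by exact moment matching.
  LPA closes the day. Draws are rejected and redrawn outside plausibility
  bounds (sleep 310–760, SB ≥ 60, LPA ≥ 95 min/day) — the same bounds
  within which the event generator can realize a day exactly. Because
  rejection truncates the proposal distribution, the generator first runs a
  short deterministic pilot that shifts the proposal centre until the
  accepted means equal the configured population means.
* **Population means** default to 443/547/419/31 min/day
  (sleep/SB/LPA/MVPA) — a sedentary working-adult profile; LPA closes the
  1440-min day.
* **Between-subject and occasion-error SDs** default to (46, 133, 31) and
  (37, 97, 22) min/day. These are derived from the typical published
  dispersion of such cohorts (observed SD ≈ 60/165/38 min/day per occasion)
  split by test-retest ICCs of about 0.6–0.65 via
  $\sigma_b = SD\sqrt{\rho}$, $\sigma_e = SD\sqrt{1-\rho}$, so the implied
  true ICC $\sigma_b^2/(\sigma_b^2+\sigma_e^2)$ is ≈ 0.61 (sleep),
  0.65 (SB), 0.66 (MVPA, raw scale).
* **The device measurement model.** The device does not measure the same
  construct as the questionnaire: it reads behaviour b as
  $\mu_b + \text{bias}_b + \lambda_b\,(s_b + \eta_b - \mu_b)$ plus
  day-level noise, where $\eta_b$ is a persistent participant-level
  construct discrepancy and $\lambda_b < 1$ compresses the between-subject
  range (device SDs in validation studies are roughly half the
  questionnaire SDs). Defaults (bias 0/96/58; λ 0.96/0.33/0.41; construct
  SD 28/215/52) are solved analytically from three emulation targets per
  behaviour: device-arm mean, device-arm SD, and the
  questionnaire-vs-device correlation (≈ 0.66/0.42/0.42). MVPA again uses
  the multiplicative form. The range compression is also what produces the
  positive proportional bias seen in Bland–Altman plots of SB and LPA: with
  attenuation λ and no noise the expected difference-on-mean slope is
  $2(1-\lambda)/(1+\lambda)$.
* **Behavioural texture.** Workdays shift SB upward by a configurable delta
  (default 40 min) with non-workdays compensating, so the weekly mean stays
  at the latent value. Naps (per-day probability 0.3, 20–60 min) appear as
  daytime sitting and in the diary. Diaries carry bed/wake jitter
  (SD 10 min). A night may begin with an in-bed upright burst
  (probability 0.25; 3–8 min of sitting then a 2-min burst) and may contain
  a brief upright interruption. Non-wear gaps occur on 30% of days with an
  expected 0.5 h/day overall; a small noncompliant fraction (5%) wears the
  device so poorly that they usually fail the 5-valid-day rule, and 9.5% of
  participants skip the second questionnaire occasion — reproducing the
  attrition accounting of a real validation cohort (≈ 126 → ≈ 114
  reliability pairs → ≈ 107 validity pairs).

The generator emits events at the bout level (sitting/standing/stepping
with cadence), which is where device processing actually starts; it does
not simulate raw 20 Hz accelerations. Other simplifications: one sleep
period per day (no split-shift sleep), no seasonal or day-of-week structure
beyond the workday SB shift, Gaussian errors for sleep/SB, and
self-consistent questionnaire responses (respondents misreport only through
the occasion error, never incoherently). Passing tests therefore
demonstrate that the *computations* are correct under controlled
conditions, not that any instrument is valid in the field.

## Numerical choices

* Internal event arithmetic is in seconds; minutes appear only in reports.
* Clock items are hh:mm, so generated rise times round the target time in
  bed to whole minutes; round-trip checks use a 1 min/day tolerance.
* Ties in the candidate-window search break to the earliest start; tie
  handling in ranks uses mid-ranks.
* Zero-variance cells: perfect agreement returns ICC = 1 with a degenerate
  (1, 1) interval; an all-constant table is an error, as is an all-tied
  vector for ρ.
* Every stochastic routine takes an explicit seed; per-participant
  sub-seeds are derived arithmetically from the cohort seed so cohorts are
  reproducible under any generation order.

## Problem sizes

The shipped analysis scripts and the acceptance script run the default
cohort (n = 126, 7 days, ≈ 53,000 events) end to end with B = 2000
bootstrap resamples. Parameter-recovery checks use 200–500 replicate
cohorts of n = 114; the ICC oracle comparison uses 1000 random datasets of
n ∈ [5, 50]. These sizes give Monte-Carlo error well below the tolerances
quoted in the tests.

## Known limitations

* The cadence→MET mapping is a single cut-point; the published regression
  equation can be slotted in but is not bundled.
* Multi-sleep (split-shift) days are out of scope; the shift-work flag
  affects nothing beyond bookkeeping, because night-shift sleep timing has
  no published distribution to emulate.
* Compositional data analysis (log-ratio reliability/validity) is
  deliberately out of scope; all statistics here are the conventional
  per-behaviour ones, which is exactly why the closure diagnostics matter.
* The questionnaire item schema is the minimal scoring-complete set, not
  the full 32-item instrument.
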