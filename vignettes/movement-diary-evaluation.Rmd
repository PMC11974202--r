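---
title: "Evaluating 24-h movement-behavior diaries against accelerometry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating 24-h movement-behavior diaries against accelerometry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

movediary evaluates a parent-reported time-use diary for 0–4-year-olds in
two respects: how much reporting is needed for reliable daily estimates of
physical activity (PA), sedentary behavior (SB) and sleep, and whether the
diary's labels are consistent with raw accelerometry. This vignette is the
package's own account of the models, the tunable parameters and the design
choices; it states no empirical result that the test suite does not itself
compute.

## The diary and its classification

The diary records one row per activity with start/stop times on a 5-min
grid (minimum duration 5 min; the reporting app proposes 30 min by
default), one of eleven categories, and follow-up questions on intensity
(playing, screen use) and posture (sitting/lying calmly, playing).
Classification into PA/SB/sleep is a deterministic function of category,
intensity, posture, the child's age group (0–6 m, 6–12 m, 1–2 y, 2–3 y,
3–4 y) and achieved motor milestones. The principle behind the
developmental adaptations: a posture that demands active postural control
at the child's stage counts as PA — lying on the tummy for 0–1-year-olds,
sitting without support once (and only once) that milestone is achieved,
standing without support between 6 months and 2 years with the milestone.
Active play is PA in any posture; personal care, eating/drinking and
passive transport are SB at every age; passive screen use is SB and active
screen use PA (defined above 6 months); active transport is PA once the
child walks without support or is older than 2 years. Three descriptive
categories ("other activity", "I don't know", "my child was with someone
else") are excluded from analysis but still document the day.

Two choices here were genuinely open:

* **Coverage.** "Hours of reported activities" is not defined anywhere
  authoritative for excluded categories. We count *all* reported entries,
  including excluded categories, toward a day's coverage — a
  "with someone else" block shows the parent did account for that time —
  and expose `coverage_includes_excluded = FALSE` for the other reading.
* **Undefined combinations.** Combinations the rule table does not define
  (active transport for a pre-walking 1-year-old, a posture belonging to
  another age band) classify to `NA` and fail loudly in `daily_totals()`
  rather than being silently coerced; a misrouted entry should surface,
  not bias totals. Likewise, overlapping entries are validation errors,
  not auto-truncated. Entries crossing midnight are split at midnight;
  days run midnight-to-midnight, and weekend means Saturday/Sunday of the
  entry's local date. Age group is fixed at the first diary date for the
  measurement week.

## Compositional coordinates

Daily PA/SB/sleep minutes are a 3-part composition; analyses use isometric
log-ratio pivot coordinates. With reference part PA,
$z_1 = \sqrt{2/3}\,\ln\!\big(\mathrm{PA}/(\mathrm{SB}\cdot\mathrm{sleep})^{1/2}\big)$ and
$z_2 = \sqrt{1/2}\,\ln(\mathrm{SB}/\mathrm{sleep})$; rotating the
reference yields ilr.SB and ilr.sleep. Only the first pivot coordinate of
each rotation enters downstream analyses; the pair exists so the
transformation is invertible, which the tests exploit as a round-trip
oracle. Zeros (possible for PA on sparse days) are handled by
multiplicative replacement with `delta = 1` minute — deliberately below
the diary's 5-min resolution so a replaced zero can never outrank a real
entry — before taking logs.

## Reliability: ICC and the Spearman–Brown prophecy

Single-day reliability is the intraclass correlation from the two-way
children × days ANOVA mean squares, single-measurement form. The default
is absolute agreement,
$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$
which charges systematic day effects against reliability; the consistency
form ICC(C,1) (which does not) is available via `icc_type =
"consistency"` because both conventions are current in this literature.
Confidence intervals use the exact F interval for ICC(C,1) and the
Satterthwaite-df approximation for ICC(A,1). Negative estimates are
reported as computed — flooring them would break the interval
construction.

The minimum number of reporting days for a target reliability (default
0.70) inverts the Spearman–Brown prophecy formula,
$k = \mathrm{target}(1-r)\,/\,r(1-\mathrm{target})$. The package checks
this empirically: the ICC of $k$-day means on simulated data matches the
stepped-up prediction within Monte-Carlo error, which is the core
justification for prescribing reporting duration from single-day ICCs.

`reliability_grid()` crosses hour criteria (12–24) with day counts (2–7).
Children with surplus qualifying days have days drawn uniformly at random;
this is repeated five times (seeded) and the ICC averaged, to keep one
arbitrary selection from driving the estimate. Two open points were
resolved as follows: day matrices are required complete per repetition
(children below the day count are excluded and counted, no pairwise ICCs),
and the reported interval is the mean of the per-repetition intervals —
a descriptive summary, not a pooled inference. Minute-scale outcomes are
log-transformed as $\ln(x+1)$ (daily minutes are right-skewed; the +1
tolerates zero-PA days); ilr coordinates enter untransformed. Note that
ICC(A,1) is not invariant to the random order in which selected days are
assigned to matrix columns, so repetition spread is small but nonzero
even without surplus days.

Weekday/weekend differences (to decide whether selections must include a
weekend day) use a linear mixed model per outcome: weekend indicator, sex
and age in months at the first diary day as fixed effects, child random
intercept, Satterthwaite p-values; a singular fit falls back to a flagged
paired within-child contrast.

## Accelerometry

Raw ±8 g, 50 Hz triaxial signals are processed in three steps, each a
deliberately simple, single-pass implementation of the standard heuristic
family:

* **Autocalibration** estimates per-axis offset and gain by iteratively
  regressing still-epoch mean vectors onto their projection on the unit
  sphere (still = all three per-axis SDs < 0.013 g in a 5-s epoch;
  at least 15 min of still data spanning ≥ 0.1 g of orientation spread
  required, else a flagged pass-through). Files with post-calibration
  error above 0.01 g are flagged for exclusion.
* **Non-wear** is a sliding 30-min window (one-epoch steps) over pooled
  per-axis SDs; a window with ≥ 2 axes below 0.013 g marks all its epochs
  non-wear. Simplified relative to multi-stage production pipelines, and
  not bit-identical to them.
* **Epoch metrics** over 5-s epochs anchored at midnight: ENMO with
  *sample-level* negative truncation, $\overline{\max(r-1,0)}$, and MAD,
  $\overline{|r-\bar r|}$, after clipping samples to ±8 g. Partial epochs
  are dropped. Both metrics depend only on the magnitude $r$, hence are
  rotation invariant — a property the tests assert.

## Diary–sensor alignment

Epochs belong to an entry when their start instant lies in
`[start, end]`, inclusive at both ends, so back-to-back entries share one
boundary epoch — the matching rule is honest about the diary's 5-min
resolution rather than arbitrating the boundary. Only wear epochs count;
an entry whose span contains no wear epoch is dropped and counted.
Per-entry medians of epoch ENMO and MAD (acceleration distributions are
strongly right-skewed) are the analysis unit, one row per entry ×
placement, with excluded-category entries summarized but flagged. A
configurable fixed clock offset supports synchronization sensitivity
checks; by default diary and device clocks are assumed synchronized.

## The hypothesis ledger

Eleven activity groupings are compared: sleep, seven predominantly-SB
groupings (sitting/lying, personal care, eating/drinking, passive
transport, passive screen use, calm play, play of unknown intensity) and
three predominantly-PA groupings (active play, active transport, active
screen use). Enumeration gives $\binom{7}{2}=21$ SB-similarity pairs,
$\binom{3}{2}=3$ PA-similarity pairs, and $10 + 3\times7 = 31$ difference
pairs (sleep below each waking grouping; each PA above each SB grouping) —
55 sub-hypotheses, plus the behavior-level main hypothesis
sleep < SB < PA.

Per metric × placement, `fit_category_model()` fits
$\ln(\mathrm{median}+\varepsilon)$ on the grouping, sex and age, with
random intercepts for child and day-within-child ($\varepsilon$ = 0.001 g:
sleep entries can have an exactly zero median; 0.001 g sits an order of
magnitude below the sedentary signal level). The per-entry median is the
observation unit (the aggregation level was ambiguous; per-entry keeps the
day-within-child term estimable), and the nested structure drops to a
child intercept, flagged, when singular. Contrasts of adjusted group
means use Satterthwaite degrees of freedom at two-tailed α = 0.05, with no
multiplicity correction across the 55 hypotheses. A similarity hypothesis
is supported when $p \ge .05$; a difference when $p < .05$ with the
expected sign. Verdicts aggregate across the four metric × placement
combinations: `+` all four, `−` none, `±` otherwise (supporting
combinations listed). Marginal $R^2$ of the fixed effects is banded as
very weak [0, .02), weak [.02, .13), moderate [.13, .26], substantial
(> .26).

## The synthetic-data generator

The generator defines the study conditions for every test, so its
defaults are fixed once:

* **Daily minutes.** Lognormal child intercepts plus normal day deviations
  on the log scale, means (PA, SB, sleep) = (240, 420, 780) min — a
  plausible toddler day — total log-SD 0.35 and between-child share
  (`icc_target`) 0.5, then closure to the 1440-min day and
  largest-remainder rounding to the 5-min grid. With a common
  between-child share across behaviors the closure approximately preserves
  that share on the minute scale, which the moment-recovery test checks.
  An optional additive weekend shift (default 0) feeds the weekend models.
* **Schedules.** Sleep is placed as a morning block (~45%), an
  early-afternoon nap (remainder) and an evening block (~35%); awake gaps
  are tiled with bouts from the bout model (default constant 30 min, the
  app's default duration), the behavior of each bout drawn in proportion
  to remaining PA/SB budgets and categories drawn from weights patterned
  on reported frequencies (eating/drinking most common, active screen use
  rare). Because budgets and segments must tile exactly, terminal bouts
  are trimmed: with the constant-30 model most but not all bouts are
  exactly 30 min.
* **Diary emission.** Coverage per day is drawn from a Beta(3, 1) model
  rescaled to 12–24 h (most parents report most of the day); entries are
  dropped in random order, the last kept entry trimmed, until reported
  minutes hit the draw exactly. Afterwards 2% / 1% of entries are
  relabeled "my child was with someone else" / "I don't know" — after
  scheduling, so truth labels remain available to oracle tests.
* **Acceleration.** Gravity is a unit vector re-oriented per activity
  interval (the discrete analog of slow re-orientation); dynamic movement
  is zero-mean Gaussian noise with per-grouping SD (sleep 0.005 g,
  sedentary 0.012–0.03 g, active 0.12–0.2 g, plus a 0.003 g sensor noise
  floor in quadrature), clipped to ±8 g. Non-wear appears as frozen
  constant blocks of 30–60 min covering ~5% of the day, matching the
  detector's window by design. The passive-transport confound — external
  vehicle/stroller vibration the diary cannot see — adds vibration in
  quadrature during passive-transport intervals: 0.25 g at the hip (set
  a priori as a typical vehicle-vibration magnitude, since no usable
  numeric levels exist to copy) with 0.3 transmission to the wrist. It is
  off by default; enabling it reproduces, as a property, the qualitative
  finding that hip acceleration during passive transport can exceed
  active play while the wrist comparison survives.

Two generation paths exist for acceleration. `simulate_raw_acceleration()`
is the sample-level model above. `simulate_epoch_series()` draws per-epoch
ENMO/MAD directly from that model's epoch-level distribution: for each
distinct noise level the epoch mean and SD of both metrics are calibrated
once by Monte Carlo on the sample-level model (400 epochs at the
configured rate, cached, own fixed seed), and epochs are then drawn as
truncated-at-zero normals. Cohort-scale studies consume only epoch
metrics, so this preserves exactly the quantities the analysis uses while
making replicate-cohort studies tractable; agreement between the two
paths at the behavior level is itself a test.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: no biomechanics beyond level-ordered noise (no
intensity spectra, no posture-specific signatures), no parent recall or
social-desirability bias, no systematic misreporting of times, no
diary–device clock drift, no idle-sleep-mode artifacts, and clean
category separations that make mixed-model R² far higher than any real
cohort would produce. Results on synthetic data bound what the pipeline
can recover under its own assumptions; they do not certify the diary.

## Numerical choices and problem sizes

Seeds are explicit everywhere; every stage derives an independent
sub-stream from the master seed, so any child-day is reproducible in
isolation and pipeline artifacts are byte-identical across re-runs. The
test suite scales its simulations to what the checks need: parameter
recovery uses 500–800 children × 4–7 days (daily tables only); the
ordering-power study uses 50 replicate cohorts of 40 children × 4 days
via the epoch-level path; the confound study uses 15 cohorts with the
vibration enabled plus 8 baseline cohorts. Individual reliability-grid
cells at small day counts carry Monte-Carlo error of a few hundredths in
the ICC; recovery assertions therefore bound the grid average tightly and
single cells loosely.

## Known limitations

The non-wear and calibration steps are single-pass simplifications, not
re-implementations of any production pipeline's exact parameterization.
ICC(A,1) depends mildly on the arbitrary ordering of selected days into
matrix columns. The hypothesis machinery assumes both placements and both
metrics are present; absent combinations count as non-supporting and are
reported rather than imputed. Posture-level contrasts are out of scope —
at realistic reporting granularity postures are too sparse to model, so
the package stops at the eleven groupings.
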