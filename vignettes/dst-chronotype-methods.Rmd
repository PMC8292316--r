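---
title: "Methods: chronotype-stratified analysis of sleep adjustment to the DST advance"
author: "chronoshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chronotype-stratified analysis of sleep adjustment to the DST advance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoshift)
```

## The question and the design

The spring daylight-saving-time (DST) transition advances the wall clock by
one hour while leaving the light environment unchanged. It is therefore a
natural experiment on circadian entrainment: everyone receives the same
abrupt one-hour phase-advance demand, and individual differences in how
quickly sleep timing re-aligns to the new clock reflect individual
differences in circadian adaptability. `chronoshift` implements a pipeline
for studying that adjustment with two data streams:

* **wearable sleep events** — one row per device-recorded sleep bout
  (subject, start, end, minutes asleep, minutes in bed), giving objective
  sleep timing for the weeks around the transition;
* **genotypes** — an allele-dosage matrix plus per-variant GWAS
  summary-statistic effect sizes for objectively measured sleep midpoint,
  from which a polygenic score (PGS) proxies each subject's chronotype
  (morningness/eveningness) without relying on self-report.

Subjects are split into PGS tertiles; the bottom tertile is the *morning*
group and the top tertile the *evening* group (a higher score predicts a
later sleep midpoint). The analysis then asks whether the two groups differ
in (i) pre-transition sleep midpoints, (ii) work-night time asleep before
vs after the transition, (iii) day-by-day onset/offset profiles across the
two weeks, and (iv) social jet lag before vs after.

## Polygenic scoring

Genotype QC runs in a fixed order: externally flagged subjects (duplicates,
reported-sex mismatches — accepted as input flags, since computing them
needs intensity data the pipeline does not model) are removed first, then
subjects with call rate below 0.99. Variant statistics are recomputed on
the retained subjects, and variants are kept only with call rate ≥ 0.98,
minor allele frequency (MAF) ≥ 0.005 and an autosomal chromosome. Scoring
additionally requires MAF ≥ 0.1 and a position outside the major
histocompatibility complex (MHC), a long-range high-LD region
conventionally excluded from polygenic scores; the window defaults to the
conventional GRCh37 span chr6:25–34 Mb (half-open) and is configurable.

The score is the weighted additive model
$$\mathrm{PGS}_i = \sum_j S_j \, G_{ij},$$
with \(S_j\) the effect-allele effect size and \(G_{ij} \in \{0,1,2\}\) the
dosage. Missing dosages contribute the variant's mean dosage
\(2\,\hat p_j\), the usual scorer behaviour, so every subject gets a score.
Scores are mean-centred and scaled to unit sample SD (denominator
\(n-1\); immaterial at cohort scale but fixed for reproducibility).
Tertiles are assigned by rank with ties broken stably by subject
identifier; when \(n \bmod 3 \neq 0\) the middle group absorbs the
remainder, so group sizes never differ by more than 2.

## Sleep-event rules

* **Nighttime:** a bout is a nighttime event iff its start time-of-day lies
  in \([18{:}00, 24{:}00) \cup [00{:}00, 06{:}00)\). The half-open
  endpoints make the day partition exact; "between 6 pm and 6 am" is
  otherwise ambiguous at the boundaries.
* **Assigned night:** the bout belongs to the evening on which it started —
  a start before 06:00 is attributed to the previous calendar day, so a
  Monday 01:30 bout is a Sunday nighttime event.
* **Windows:** the pre-DST week is the Saturday eight days before the
  transition Sunday through the Friday before it; the post-DST week is the
  transition Sunday through the following Saturday. Each window contains
  every weekday exactly once, and the Saturday night immediately preceding
  the transition belongs to neither. Windows are anchored to the configured
  transition date; 2019-03-10 yields 2019-03-02…03-08 and
  2019-03-10…03-16.
* **Duration filter:** bouts with *minutes asleep* strictly below 240 are
  rejected (a 240-minute bout is kept). Minutes asleep, not wall-clock
  span, is filtered: short bouts typically reflect interruptions, and the
  wall-clock span is distorted on the transition night.
* **Pairing:** for each weekday independently, a subject's events on that
  weekday enter the before/after analyses only if the subject has at least
  one retained nighttime event on that weekday in both windows. The
  duration filter runs before pairing; pairing on unfiltered events would
  re-admit subjects whose only event is a truncated bout. A regression test
  pins this order.
* **Multiple bouts per night** are all retained — no deduplication rule is
  imposed — and enter per-cell means individually.
* **Work/free conventions:** the profile analyses use work =
  Sunday–Thursday, free = Friday–Saturday; the social-jet-lag analysis uses
  work = Monday–Thursday, free = Friday–Saturday with Sunday unlabelled.

## Circular statistics

Clock times are angles: \(\theta = t \cdot 2\pi/24\), midnight at 0, noon
at \(\pi\). All time-of-day aggregation routes through vector averaging —
the mean direction of \((\cos\theta_i, \sin\theta_i)\) — never through the
arithmetic mean of hours, which fails for samples straddling midnight
(`{23:30, 00:30}` must average to 00:00, not 12:00; a regression test
asserts exactly this). Bout midpoints are computed along the bout:
onset plus half the (mod-24) duration.

Group mean directions are compared with the parametric Watson–Williams
multisample test. With per-group un-normalised resultants
\(R_i = n_i r_i\) and pooled resultant \(R\),
$$F = K\,\frac{(N-k)\left(\sum_i R_i - R\right)}{(k-1)\left(N - \sum_i R_i\right)},
\qquad K = 1 + \frac{3}{8\hat\kappa},$$
referred to \(F_{k-1,\,N-k}\). The von Mises concentration \(\hat\kappa\)
is estimated from the pooled weighted mean resultant length
\(\bar r = \sum_i R_i / N\) by the standard three-regime closed-form
approximation (`estimate_kappa`). Published regime cut-points vary by a few
hundredths around the lower seam; this implementation switches from the
small-\(r\) series to the mid-\(r\) formula at \(r = 0.5\), where the two
formulas differ by under 0.5% — far below the sampling noise of any
resultant the test consumes — and no small-sample correction is applied.
Exact numerical parity with any particular toolbox's \(\hat\kappa\) is
therefore not claimed; the test statistic is validated instead against an
independently coded step-by-step oracle (to 1e-10) and by its empirical
size under a simulated null (two von Mises samples, common mean,
\(\kappa = 5\), \(n = 50\) each: rejection rate at \(\alpha = 0.05\) within
[0.03, 0.07] over 1,000 replicates). Pooled \(\bar r < 0.45\) triggers a
warning — the F approximation is doubtful for diffuse data — but still
returns a result, since sleep times are concentrated in practice and
synthetic edge cases must not crash.

## Comparisons and sign conventions

Work-night minutes asleep and per-subject social jet lag are compared
before vs after the transition with a two-sample t-test on linear minutes.
Welch's unequal-variance form is the default (the safer choice when cell
variances are not known to match); `var_equal = TRUE` restores the pooled
Student form. All t statistics are oriented **after − before**, so a
post-DST decrease in sleep is negative and a post-DST increase in social
jet lag positive. Social jet lag itself is the signed wrapped difference
free-mean − work-mean midpoint, mapped to \((-720, 720]\) minutes; a
subject enters a window iff it has at least one work-night and one
free-night event there, and need not appear in both windows. The pre-DST
midpoint distribution tests use every retained nighttime event with
assigned night strictly before the transition (not only the final week) and
no pairing rule, which is described only for the week-vs-week analyses.
`welch_t_summary()` reconstructs a Welch t from printed means/SEMs/sizes,
for checking published comparisons where raw data are unavailable. No
multiple-testing correction is applied; p-values are reported unadjusted at
\(\alpha = 0.05\).

## The synthetic cohort generator

Real cohorts of this kind are access-restricted, so the generator is a
first-class module that fabricates the full study structure, and every
downstream stage is validated against it.

* **Genotypes:** per-variant effect-allele frequencies uniform in
  `maf_range`, Hardy–Weinberg dosages, Gaussian effect sizes
  (`effect_size_sd`, minutes per allele), and a configurable fraction of
  variants placed inside the MHC window so the scoring exclusion is
  exercised.
* **Latent chronotype:** latent midpoint = `baseline_midpoint` +
  \(a z\) + Gaussian noise, where \(z\) is the standardized true score, the
  noise SD is `midpoint_sd` and
  \(a = (\texttt{midpoint\_sd}/60)\sqrt{f/(1-f)}\) makes the score–midpoint
  \(r^2\) equal `genetic_signal_fraction` \(= f\) in expectation. \(f = 1\)
  is the exact noise-free limit (midpoint affine in the score). The default
  \(f = 0.3\) is deliberately larger than the variance a real sleep-midpoint
  PGS explains: it gives the synthetic cohort clearly separated tertiles so
  that recovery properties are testable at a few hundred subjects.
* **Schedule:** one candidate bout per subject for each of the 15 nights
  from the Saturday eight days before the transition through the Saturday
  after it, centred on the latent midpoint with night-level Gaussian jitter
  (`onset_jitter_sd`); Friday/Saturday nights are delayed by
  `free_night_delay` for everyone in both weeks, which is what produces
  baseline social jet lag.
* **Post-DST dynamics:** from the transition Sunday, night \(d\) (days
  since transition) carries a delay decaying piecewise-linearly from the
  full skipped hour: \(\Delta(d) = T + (60 - T)\max(0, 1 -
  d/\texttt{adjust\_days\_morning})\) minutes, with target \(T = 0\) for
  the morning tertile, \(T = \texttt{persistent\_delay\_evening}\) for the
  evening tertile, and \(T/2\) for the middle tertile. The piecewise-linear
  shape is the simplest that yields the delayed-then-recovered pattern; no
  functional form is dictated by the underlying behaviour. On free nights
  the whole bout shifts by \(\Delta\); on work nights only the onset shifts
  while the offset stays pinned by the work schedule, so minutes asleep
  shrink by \(\Delta\). This asymmetry is what simultaneously produces the
  three observed signatures: persistent evening-group onset delays, an
  evening-group drop in work-night time asleep, and a post-DST rise in
  evening-group social jet lag (free midpoints shift by \(\Delta\), work
  midpoints by only \(\Delta/2\)).
* **Dropout:** with probability `short_event_rate` a bout is truncated to
  an asleep duration uniform in [60, 235] minutes — the 60-minute floor
  avoids degenerate bouts while guaranteeing failure of the 240-minute
  filter; with probability `missing_night_rate` the night emits no event.
* **The skipped hour:** the transition-night bout is generated in standard
  time and emitted in wall-clock time: timestamps at or after the 02:00
  transition instant are printed one hour ahead, so the printed span
  exceeds the true span by the skipped hour while
  `minutes_asleep`/`minutes_in_bed` keep true elapsed time, as a device
  reports them.
* **Labels:** generation uses tertiles of the TRUE score; the pipeline
  re-derives tertiles from the estimated PGS, so label agreement
  (> 60% at \(f \ge 0.3\), \(n \ge 500\)) is itself a tested property.

Default condition values: 800 subjects (the scale of the motivating intern
cohort), baseline midpoint 03:24, between-subject midpoint SD 40 min,
night-level jitter 20 min, mean asleep 410 ± 40 min, free-night delay
50 min, morning re-entrainment in 2 days, evening persistent delay 45 min,
short-bout rate 0.08 (roughly the one-in-ten loss the four-hour filter
produces in practice) and missing-night rate 0.05. Dropout rates are free
parameters — per-subject event counts are not published for the real
cohort — chosen once at plausible wearable-compliance levels.

What the generator does **not** emulate: light exposure, sleep staging,
naps with realistic daytime structure, weekday-dependent duration effects,
autocorrelated night-to-night timing, ancestry structure or linkage
disequilibrium between variants. Passing recovery tests therefore show the
pipeline correctly measures the dynamics it is pointed at, not that real
populations follow these dynamics.

## Numerical choices and degenerate inputs

All timestamps are parsed and formatted as zone-less local wall-clock time
(internally anchored in UTC so no hidden timezone rule ever fires); the
clock change is handled explicitly as described above. Weekday names are
computed locale-independently. Determinism: a single integer seed drives
all generation, and identical seed + configuration gives byte-identical CSV
and report output; re-running the analysis on the same inputs is
byte-identical too. Degenerate inputs fail loudly and specifically: empty
angle series, zero-duration bouts, constant scores, fewer than three
subjects for tertiles, all-subjects-removed QC, zero scorable variants, and
resultant length 1 (infinite concentration) each raise a distinct error;
an exactly-uniform angle sample (resultant ≈ 0) warns that the mean
direction is undefined rather than inventing one.

## Problem sizes in the tests

The validation suite runs cohorts of 250–2,000 subjects and 40–300
variants: large enough that binomial/Monte-Carlo bounds are sharp
(allele-frequency recovery within ±0.02 at n = 10,000; \(r^2\) within
±0.05 at n = 2,000), small enough that the whole suite completes in well
under a minute. The replicate-recovery experiments use 20 cohorts of 250
subjects, which recover the configured 45-minute evening Friday onset delay
to within ±5 min on average and reproduce the directional social-jet-lag
pattern (evening increase exceeding the morning change) in every replicate.

## Known limitations

* The Watson–Williams test assumes von Mises samples with common
  concentration; the implementation warns rather than refuses at low
  concentration, and its \(\hat\kappa\) is an approximation (see above).
* Sex-mismatch and duplicate QC are pass-through flags, not computed.
* Clumping/LD-aware scoring, ancestry principal components and multiple
  p-value thresholds are out of scope; the score uses all passing variants.
* The autumn (fall-back) transition, geographic/photoperiod covariates and
  longitudinal mixed models are not implemented.
* Whether observed re-alignment reflects entrainment of the internal clock
  or masking by external constraints cannot be decided from these data
  alone; the pipeline measures behaviour, not pacemaker phase.
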