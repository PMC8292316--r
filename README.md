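# chronoshift

Chronotype-stratified analysis of how sleep/wake timing adjusts to the
spring daylight-saving-time (DST) clock advance.

The spring transition moves the wall clock forward one hour while the light
environment stays put, making it a population-scale natural experiment on
circadian entrainment. `chronoshift` is for sleep/circadian researchers who
have (or want to prototype against) two data streams: device-recorded sleep
bouts (start, end, minutes asleep, minutes in bed) and genotypes with GWAS
summary-statistic effect sizes for objectively measured sleep midpoint. The
package groups subjects by a sleep-midpoint polygenic score into morning,
middle and evening tertiles and quantifies how differently the morning and
evening groups re-align their sleep to the new clock.

## What it computes

* **Polygenic score and groups** — genotype QC (sample call rate ≥ 0.99,
  then variant call rate ≥ 0.98, MAF ≥ 0.005, autosomes only), then the
  weighted additive score

  PGS_i = Σ_j S_j · G_ij

  over variants with MAF ≥ 0.1 outside the MHC region (G = effect-allele
  dosage 0/1/2, missing imputed at 2·MAF), standardized to mean 0, SD 1,
  and split into tertiles (bottom = morning, top = evening).
* **Sleep-event classification** — nighttime iff the bout starts in
  [18:00, 06:00); bouts starting before 06:00 belong to the previous
  night; pre-DST window = the Saturday eight days before the transition
  Sunday through the Friday before it, post-DST window = the transition
  Sunday through the following Saturday; bouts under 4 h asleep rejected;
  per-weekday same-subject pairing across the two windows.
* **Circular statistics** — clock times as angles (θ = t·2π/24), circular
  means and bout midpoints, von Mises concentration κ̂, and the parametric
  Watson–Williams multisample F test with correction factor 1 + 3/(8κ̂).
* **Result layers** — Table-1-style event counts; before/after work-night
  minutes-asleep t-tests per group; circular daily onset/offset/midpoint
  profiles and their wrapped before/after differences; pre-DST midpoint
  distribution tests (morning vs evening, work and free nights); and
  per-subject social jet lag (free-night minus work-night mean midpoint,
  signed wrapped minutes) compared before vs after per group.
* **A synthetic-cohort generator** — genotypes with a true additive effect
  on a latent sleep midpoint, plus two weeks of nightly events around a
  configurable transition date with group-dependent adjustment dynamics,
  short interrupted bouts and missing nights — so the entire pipeline runs
  and is validated without access to restricted cohort data.

## Worked example

```r
library(chronoshift)

cfg    <- cohort_config(n_subjects = 400, n_variants = 300, seed = 42)
cohort <- simulate_cohort(cfg)
report <- run_full_analysis(cohort$events, cohort$genotypes, run_config())
report
```

```
DST chronotype analysis report
==============================
Groups: morning 133, middle 134, evening 133 

Minutes asleep on work nights, morning group (after - before DST)
  before 410.74 ± 1.83 (n = 510); after 387.59 ± 2.09 (n = 510)
  t = -8.3259, p = 2.728e-16
Minutes asleep on work nights, evening group (after - before DST)
  before 410.67 ± 1.73 (n = 521); after 358.99 ± 1.75 (n = 521)
  t = -20.9761, p = 9.524e-82

Pre-DST midpoint tests (morning vs evening):
  work nights: means 02:57 vs 03:52, F = 427.623, p = 2.89e-81
  free nights: means 04:00 vs 04:52, F = 185.148, p = 1.61e-37

Social jet lag:
Social jet lag (min), morning group (after - before DST)
  before 51.15 ± 1.74 (n = 130); after 47.31 ± 1.52 (n = 132)
  t = -1.6611, p = 0.09791
Social jet lag (min), evening group (after - before DST)
  before 49.99 ± 1.69 (n = 131); after 67.71 ± 1.82 (n = 131)
  t = 7.1358, p = 9.695e-12
```

Reading it: tertiles split 400 subjects 133/134/133. The pre-DST circular
mean midpoints separate the groups (02:57 vs 03:52 on work nights; the
Watson–Williams F tests that separation). This cohort was generated with
the evening tertile retaining a 45-minute post-DST delay while the morning
tertile re-entrains in 2 days, and the report shows the consequences: both
groups lose work-night sleep the week after (t oriented after − before, so
negative means less sleep), the evening group losing more, and social jet
lag rises only in the evening group (50 → 68 min; the morning group's
change is small and not significant). `write_report(report, "out/")` writes
the counts/profile/SJL tables as TSV, every test as `summary.json`, and a
run log with each filter's removal counts.

All t statistics are after − before; SJL is free − work in signed wrapped
minutes. `daily_profiles()` / `profile_differences()` expose the day-by-day
onset/offset shifts behind the group contrast.

## Layout

* `R/` — circular statistics, genotype QC/PGS, event classification,
  DST analyses, synthetic cohort, I/O.
* `tests/testthat/` — unit, property and end-to-end validation tests,
  including an independently coded Watson–Williams oracle.
* `vignettes/dst-chronotype-methods.Rmd` — the methods vignette: model,
  assumptions, parameter defaults, generator scope, numerical choices,
  limitations.
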