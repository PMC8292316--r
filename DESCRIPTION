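Package: chronoshift
Title: Chronotype-Stratified Analysis of Sleep Adjustment to the Daylight Saving Time Advance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how genetically inferred chronotype modulates the
    adjustment of sleep/wake timing to the spring daylight-saving-time (DST)
    clock advance, using wearable-device sleep events as the phenotype and a
    polygenic score for objectively measured sleep midpoint as the grouping
    variable. Provides genotype quality control and weighted additive polygenic
    scoring with tertile (morning/middle/evening) grouping; classification of
    device-recorded sleep bouts into nighttime events with assigned weekdays
    and pre/post-DST windows; circular statistics for time-of-day data
    including the parametric Watson-Williams multisample test; pre/post-DST
    comparisons of time asleep, daily sleep onset/offset profiles, and social
    jet lag; and a fully deterministic synthetic-cohort generator so the whole
    pipeline can be exercised and validated without access to restricted
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
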