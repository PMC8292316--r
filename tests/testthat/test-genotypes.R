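test_that("QC removes flagged subjects, low-call-rate subjects, then failing variants, in that order", {
  set.seed(11)
  n <- 125
  m <- 200
  dos <- matrix(rbinom(n * m, 2, 0.3), n, m)
  # subject 2: call rate 98.5% (< 99%) -> excluded
  dos[2, 1:3] <- NA
  # variant 5: exactly one effect allele among the 124 retained subjects
  # -> MAF 1/248 ~ 0.004 < 0.005 -> excluded
  dos[, 5] <- 0
  dos[10, 5] <- 1
  # variant 6: two copies -> MAF ~ 0.008 -> kept
  dos[, 6] <- 0
  dos[10, 6] <- 2
  # variant 7: poor call rate on retained subjects
  dos[3:7, 7] <- NA

  gs <- make_genotypes(dos, effect_size = rep(0.1, m))
  gs$exclusion_flags <- data.frame(subject_id = "S01", reason = "duplicate")
  qc <- qc_filter(gs, qc_thresholds())

  expect_false("S01" %in% qc$subjects)  # flagged
  expect_false("S02" %in% qc$subjects)  # 98.5% call rate
  expect_equal(length(qc$subjects), n - 2)
  expect_false("v005" %in% qc$variants$variant_id)
  expect_true("v006" %in% qc$variants$variant_id)
  expect_false("v007" %in% qc$variants$variant_id)  # call rate 118/123 < 0.98

  log <- attr(qc, "qc_log")
  expect_equal(log$removed[log$step == "subjects_flagged"], 1)
  expect_equal(log$removed[log$step == "subjects_low_call_rate"], 1)
})

test_that("QC passes complete unflagged data through unchanged and drops non-autosomes", {
  dos <- matrix(rep(c(0, 1, 2, 1), 5), 4, 5)
  gs <- make_genotypes(dos, effect_size = 1:5,
                       chrom = c("1", "2", "X", "3", "4"))
  qc <- qc_filter(gs, qc_thresholds())
  expect_equal(qc$subjects, gs$subjects)
  expect_equal(qc$variants$variant_id,
               gs$variants$variant_id[gs$variants$chrom != "X"])
  expect_equal(unname(qc$dosages[, "v001"]), c(0, 1, 2, 1))
})

test_that("QC is monotone: relaxing thresholds never removes more", {
  set.seed(12)
  dos <- matrix(rbinom(60 * 80, 2, runif(80, 0.02, 0.5)[rep(1:80, each = 60)]),
                60, 80, byrow = FALSE)
  dos[sample(length(dos), 200)] <- NA
  gs <- make_genotypes(dos, effect_size = rnorm(80))
  # relaxing the variant thresholds at a fixed sample threshold never drops
  # more variants (variant statistics are computed on the same subjects)
  strictv <- qc_filter(gs, qc_thresholds(sample_call_rate_min = 0.95,
                                         variant_call_rate_min = 0.98,
                                         maf_min_qc = 0.05))
  laxv <- qc_filter(gs, qc_thresholds(sample_call_rate_min = 0.95,
                                      variant_call_rate_min = 0.90,
                                      maf_min_qc = 0.005))
  expect_identical(strictv$subjects, laxv$subjects)
  expect_true(all(strictv$variants$variant_id %in% laxv$variants$variant_id))
  # relaxing the sample threshold never drops more subjects
  laxs <- qc_filter(gs, qc_thresholds(sample_call_rate_min = 0.90))
  stricts <- qc_filter(gs, qc_thresholds(sample_call_rate_min = 0.99))
  expect_true(all(stricts$subjects %in% laxs$subjects))
})

test_that("polygenic score is the hand-checkable weighted dosage sum", {
  # 4 subjects x 3 common variants; subject 1 has G = (2, 1, 0)
  dos <- rbind(c(2, 1, 0), c(1, 1, 1), c(0, 2, 1), c(1, 0, 2))
  gs <- make_genotypes(dos, effect_size = c(0.1, -0.2, 0.3))
  raw <- compute_pgs(gs, qc_thresholds())
  expect_equal(unname(raw["S01"]), 0.1 * 2 - 0.2 * 1 + 0.3 * 0)
  expect_equal(unname(raw["S04"]), 0.1 * 1 - 0.2 * 0 + 0.3 * 2)

  # null weights and linearity
  gs0 <- gs
  gs0$variants$effect_size <- 0
  expect_true(all(compute_pgs(gs0, qc_thresholds()) == 0))
  gs2 <- gs
  gs2$variants$effect_size <- 2 * gs$variants$effect_size
  expect_equal(compute_pgs(gs2, qc_thresholds()),
               2 * raw, ignore_attr = TRUE)

  # invariant to variant ordering
  perm <- c(3, 1, 2)
  gsp <- genotype_set(gs$dosages[, perm], gs$variants[perm, ], gs$subjects)
  expect_equal(unname(compute_pgs(gsp, qc_thresholds())), unname(raw))
})

test_that("scoring excludes MHC and low-MAF variants and mean-imputes missing dosages", {
  dos <- rbind(c(2, 1, 1), c(1, 1, 0), c(0, 2, 1), c(1, 0, 2))
  # variant 2 inside the MHC window (chr6, 30 Mb); variant 3 at exactly the
  # half-open end (34 Mb) stays in
  gs <- make_genotypes(dos, effect_size = c(1, 10, 100),
                       chrom = c("1", "6", "6"),
                       pos = c(1e6, 30e6, 34e6))
  raw <- compute_pgs(gs, qc_thresholds())
  expect_equal(as.vector(unname(raw)), drop(dos[, c(1, 3)] %*% c(1, 100)))

  # a missing dosage contributes 2 * allele frequency of the variant
  dosm <- dos
  dosm[1, 1] <- NA
  gsm <- make_genotypes(dosm, effect_size = c(1, 10, 100),
                        chrom = c("1", "6", "6"), pos = c(1e6, 30e6, 34e6))
  af <- sum(dosm[2:4, 1]) / 6
  expect_equal(unname(compute_pgs(gsm, qc_thresholds())["S01"]),
               2 * af * 1 + 100 * 1)

  # no variant passes -> error
  gs_rare <- make_genotypes(rbind(c(0, 0), c(0, 0), c(1, 0), c(0, 1)),
                            effect_size = c(1, 1))
  expect_error(compute_pgs(gs_rare, qc_thresholds(pgs_maf_min = 0.4)),
               "no variants")
})

test_that("standardization gives mean 0, SD 1 and is idempotent and affine-invariant", {
  z <- standardize_scores(c(1, 2, 3))
  expect_equal(unname(z), c(-1, 0, 1))
  expect_equal(standardize_scores(z), z, tolerance = 1e-12)

  set.seed(5)
  x <- rnorm(50)
  expect_equal(standardize_scores(3.2 * x + 7), standardize_scores(x),
               tolerance = 1e-12)
  zz <- standardize_scores(x)
  expect_lt(abs(mean(zz)), 1e-9)
  expect_lt(abs(sd(zz) - 1), 1e-9)
  expect_error(standardize_scores(rep(2, 10)), "constant")
})

test_that("tertile assignment splits bottom/middle/top with the middle absorbing the remainder", {
  s <- setNames(c(5, 1, 9, 3, 7, 2, 8, 4, 6), paste0("S", 1:9))
  g <- assign_tertiles(s)
  expect_equal(as.integer(table(g)), c(3L, 3L, 3L))
  expect_setequal(names(s)[s >= 7], names(g)[g == "evening"])
  expect_setequal(names(s)[s <= 3], names(g)[g == "morning"])

  g10 <- assign_tertiles(setNames(rnorm(10), sprintf("T%02d", 1:10)))
  expect_equal(as.integer(table(g10)), c(3L, 4L, 3L))

  # all-tied scores: assignment determined by identifier order
  tied <- assign_tertiles(setNames(rep(0, 7), sprintf("A%d", 1:7)))
  expect_equal(as.character(tied[c("A1", "A2")]), c("morning", "morning"))
  expect_equal(as.character(tied[c("A6", "A7")]), c("evening", "evening"))
  expect_equal(as.integer(table(tied)), c(2L, 3L, 2L))

  expect_error(assign_tertiles(c(a = 1, b = 2)), "at least 3")
})

test_that("estimated-PGS tertiles track true-score tertiles and order latent midpoints", {
  cfg <- cohort_config(n_subjects = 500, n_variants = 300,
                       genetic_signal_fraction = 0.3, seed = 101)
  gen <- generate_genotypes(cfg)
  latent <- generate_latent_chronotype(gen, cfg)
  true_grp <- assign_tertiles(attr(latent, "true_score_z"))

  pgs <- pgs_pipeline(gen, qc_thresholds())
  est_grp <- setNames(as.character(pgs$group), pgs$subject_id)
  agree <- mean(est_grp[names(true_grp)] == as.character(true_grp))
  expect_gt(agree, 0.6)

  m <- mean(latent[pgs$subject_id[pgs$group == "morning"]])
  e <- mean(latent[pgs$subject_id[pgs$group == "evening"]])
  expect_lt(m, e)
})
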