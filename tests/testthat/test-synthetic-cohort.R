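test_that("perfect indicators reproduce the latent indication exactly", {
  cfg <- synthetic_config(n_patients = 500, prevalence = 0.4,
                          indicator_sens = c(1, 1, 1), indicator_spec = c(1, 1, 1),
                          feature_probs = list(), seed = 3)
  co <- generate_cohort(cfg)
  for (j in 1:3) {
    expect_identical(co$indicators[[paste0("ind", j)]], co$truth$latent_indication)
  }
})

test_that("empirical indicator marginals match the closed-form mixture marginal", {
  # marginal of indicator j: pi*S_j + (1-pi)*(1-C_j)
  cfg <- synthetic_config(n_patients = 100000, prevalence = 0.45,
                          indicator_sens = c(0.95, 0.8, 0.8),
                          indicator_spec = c(0.95, 0.7, 0.7),
                          feature_probs = list(), seed = 11)
  co <- generate_cohort(cfg)
  expected <- 0.45 * c(0.95, 0.8, 0.8) + 0.55 * (1 - c(0.95, 0.7, 0.7))
  expect_equal(unname(colMeans(co$indicators[c("ind1", "ind2", "ind3")])),
               expected, tolerance = 0.005 / max(expected))
  expect_equal(mean(co$indicators$ind1), 0.455, tolerance = 0.005 / 0.455)
})

test_that("within-class correlation of indicators 2 and 3 vanishes when covariance is 0", {
  cfg <- synthetic_config(n_patients = 100000, prevalence = 0.45,
                          feature_probs = list(), seed = 19)
  co <- generate_cohort(cfg)
  for (cls in 0:1) {
    sel <- co$truth$latent_indication == cls
    r <- cor(co$indicators$ind2[sel], co$indicators$ind3[sel])
    expect_lt(abs(r), 0.02)
  }
})

test_that("configured within-class covariance is realized empirically", {
  cfg <- synthetic_config(n_patients = 100000, dep_cov_pos = 0.03,
                          dep_cov_neg = 0.02, feature_probs = list(), seed = 23)
  co <- generate_cohort(cfg)
  sel <- co$truth$latent_indication == 1
  expect_equal(cov(co$indicators$ind2[sel], co$indicators$ind3[sel]), 0.03,
               tolerance = 0.1)
  expect_equal(cov(co$indicators$ind2[!sel], co$indicators$ind3[!sel]), 0.02,
               tolerance = 0.15)
})

test_that("claims flag frequencies match the calibrated marginals", {
  cfg <- default_synthetic_config(seed = 5)
  cfg$n_patients <- 100000L
  co <- generate_cohort(cfg)
  # published frequency table the generator is calibrated to
  target <- published_counts()$claims_flags / published_counts()$eligible
  got <- colMeans(co$flags)[names(target)]
  expect_equal(unname(got), unname(target), tolerance = 0.03)
  expect_equal(unname(got["colonoscopy"]), 0.217, tolerance = 0.015)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(synthetic_config(prevalence = 1.2), "prevalence")
  expect_error(synthetic_config(indicator_sens = c(0.9, -0.1, 0.8)), "indicator_sens")
  expect_error(synthetic_config(feature_probs = list(colonoscopy = c(0.2, 1.4))),
               "colonoscopy")
  expect_error(synthetic_config(dep_cov_pos = 0.9), "dep_cov_pos")
  expect_error(synthetic_config(n_patients = 0), "n_patients")
})

test_that("identical seeds give byte-identical output files", {
  dir1 <- file.path(tempdir(), "coh1"); dir2 <- file.path(tempdir(), "coh2")
  cfg <- default_synthetic_config(seed = 77)
  cfg$n_patients <- 150L
  write_cohort(generate_cohort(cfg), dir1)
  write_cohort(generate_cohort(cfg), dir2)
  for (f in c("truth.csv", "indicators.csv", "claims.csv")) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  }
})

test_that("pattern counts tabulate correctly and conserve the cohort size", {
  ind <- data.frame(patient_id = 1:4,
                    ind1 = c(1, 1, 0, 1), ind2 = c(1, 1, 0, 0), ind3 = c(1, 1, 0, 0))
  pc <- pattern_counts(ind)
  expect_identical(pc[["111"]], 2L)
  expect_identical(pc[["000"]], 1L)
  expect_identical(pc[["100"]], 1L)
  expect_identical(sum(pc), 4L)
  expect_true(all(pc[setdiff(names(pc), c("111", "000", "100"))] == 0L))

  empty <- data.frame(patient_id = character(), ind1 = integer(),
                      ind2 = integer(), ind3 = integer())
  expect_identical(sum(pattern_counts(empty)), 0L)

  cfg <- default_synthetic_config(seed = 2); cfg$n_patients <- 1230L
  co <- generate_cohort(cfg)
  expect_identical(sum(pattern_counts(co$indicators)), 1230L)
})

test_that("missing indicator values error with the offending patients listed", {
  ind <- data.frame(patient_id = c("A", "B"), ind1 = c(1, NA), ind2 = c(0, 1),
                    ind3 = c(0, 1))
  expect_error(pattern_counts(ind), "B")
})
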