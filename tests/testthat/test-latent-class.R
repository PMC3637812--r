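make_counts <- function(...) {
  counts <- stats::setNames(integer(8),
                            c("000", "001", "010", "011", "100", "101", "110", "111"))
  given <- list(...)
  counts[names(given)] <- as.integer(unlist(given))
  counts
}

test_that("cell probabilities match hand arithmetic and normalize", {
  p <- lca_params(0.5, c(1, 1, 1), c(1, 1, 1))
  expect_equal(cell_probability(c(1, 1, 1), p), 0.5)
  expect_equal(cell_probability("000", p), 0.5)

  p2 <- lca_params(0.44, c(0.9, 0.8, 0.7), c(0.9, 0.7, 0.8))
  expect_equal(cell_probability(c(1, 1, 1), p2),
               0.44 * 0.9 * 0.8 * 0.7 + 0.56 * 0.1 * 0.3 * 0.2)  # = 0.22512
  expect_equal(sum(cell_probabilities(p2)), 1)

  set.seed(42)
  for (i in 1:25) {
    S <- runif(3, 0.5, 1); C <- runif(3, 0.5, 1)
    rngp <- screenlca:::cov_range(S[2], S[3])
    rngn <- screenlca:::cov_range(1 - C[2], 1 - C[3])
    pp <- lca_params(runif(1), S, C,
                     cov_pos = runif(1, rngp[1], rngp[2]),
                     cov_neg = runif(1, rngn[1], rngn[2]))
    expect_equal(sum(cell_probabilities(pp)), 1, tolerance = 1e-12)
    expect_true(all(cell_probabilities(pp) >= 0))
  }
})

test_that("dependence model with zero covariances equals the independence model", {
  p_ind <- lca_params(0.44, c(0.9, 0.8, 0.7), c(0.9, 0.7, 0.8))
  p_dep <- lca_params(0.44, c(0.9, 0.8, 0.7), c(0.9, 0.7, 0.8),
                      cov_pos = 0, cov_neg = 0)
  expect_identical(cell_probabilities(p_ind), cell_probabilities(p_dep))
})

test_that("covariances outside the valid range are rejected", {
  expect_error(lca_params(0.5, c(0.9, 0.8, 0.7), c(0.9, 0.7, 0.8), cov_pos = 0.5),
               "cov_pos")
  expect_error(lca_params(0.5, c(0.9, 0.8, 0.7), c(0.9, 0.7, 0.8), cov_neg = -0.9),
               "cov_neg")
})

test_that("log likelihood matches direct evaluation and flags empty cells", {
  p <- lca_params(0.5, c(1, 1, 1), c(1, 1, 1))
  counts <- make_counts(`111` = 20)
  expect_equal(log_likelihood(counts, p), 20 * log(0.5))

  p2 <- lca_params(0.44, c(0.9, 0.8, 0.7), c(0.9, 0.7, 0.8))
  counts2 <- make_counts(`111` = 2, `000` = 2)
  expect_equal(log_likelihood(counts2, p2),
               2 * log(cell_probability("111", p2)) + 2 * log(cell_probability("000", p2)))

  # perfect tests give pattern 110 probability zero
  expect_warning(ll <- log_likelihood(make_counts(`110` = 1), p), "zero")
  expect_identical(ll, -Inf)
})

test_that("likelihood is invariant under the label-switching symmetry", {
  # (pi, S, C) -> (1 - pi, 1 - C, 1 - S) leaves every cell probability fixed
  set.seed(7)
  for (i in 1:20) {
    S <- runif(3); C <- runif(3); pi <- runif(1)
    counts <- make_counts(`111` = rpois(1, 50), `000` = rpois(1, 50),
                          `101` = rpois(1, 20), `010` = rpois(1, 20))
    a <- log_likelihood(counts, lca_params(pi, S, C))
    b <- log_likelihood(counts, lca_params(1 - pi, 1 - C, 1 - S))
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("prior coverage reproduces the elicited prior statements", {
  expect_equal(prior_coverage(10.67, 1.06, 0.70, 1.00), 0.975, tolerance = 1e-3)
  expect_equal(prior_coverage(6, 7.6, 0.20, 0.70), 0.95, tolerance = 1e-3)
  expect_equal(prior_coverage(2.3, 4.5, 0, 1), 1)
  expect_error(prior_coverage(-1, 2, 0, 1), "beta")
  expect_error(prior_coverage(1, 2, 0.5, 0.2), "lo")
})

test_that("prior-only Gibbs run reproduces the prevalence prior", {
  d <- gibbs_sample(make_counts(), mcmc = mcmc_control(1, 5000, 1000, 2), seed = 8)
  # with no data the augmented-data updates draw from Beta(6, 7.6) directly
  expect_equal(mean(d$draws[, "prevalence"]), 6 / 13.6, tolerance = 0.01)
  expect_equal(sd(d$draws[, "prevalence"]),
               sqrt(6 * 7.6 / (13.6^2 * 14.6)), tolerance = 0.05)
})

test_that("all retained draws satisfy the identifiability constraint", {
  cfg <- default_synthetic_config(seed = 31); cfg$n_patients <- 400L
  co <- generate_cohort(cfg)
  d <- gibbs_sample(pattern_counts(co$indicators),
                    mcmc = mcmc_control(1, 2000, 500, 2), seed = 9)
  for (j in 1:3) {
    expect_true(all(d$draws[, paste0("sens", j)] + d$draws[, paste0("spec", j)] > 1))
  }
  expect_true(all(d$draws[, 1:7] >= 0 & d$draws[, 1:7] <= 1))
})

test_that("Gibbs sampling is reproducible given a seed", {
  counts <- make_counts(`111` = 40, `110` = 20, `000` = 35, `001` = 10)
  d1 <- gibbs_sample(counts, mcmc = mcmc_control(2, 1500, 500, 5), seed = 21)
  d2 <- gibbs_sample(counts, mcmc = mcmc_control(2, 1500, 500, 5), seed = 21)
  expect_identical(d1$draws, d2$draws)
  expect_identical(nrow(d1$draws), 2L * ((1500L - 500L) %/% 5L))
})

test_that("posterior mean prevalence matches the grid-integration oracle on tiny counts", {
  counts <- make_counts(`111` = 5, `000` = 5)
  d <- gibbs_sample(counts, seed = 5)
  oracle <- grid_posterior_mean_prev(5, 5, lca_priors(), grid = 800)
  expect_equal(mean(d$draws[, "prevalence"]), oracle, tolerance = 0.02 / oracle)
})

test_that("pattern posteriors match the plug-in formula for a single draw", {
  d <- single_draw(0.44, c(0.9, 0.8, 0.7), c(0.9, 0.7, 0.8))
  pp <- pattern_posterior(d)
  expect_equal(pp$median_prob[pp$pattern == "111"], 0.22176 / 0.22512, tolerance = 1e-10)
  expect_identical(pp$label[pp$pattern == "111"], "screening")

  perfect <- single_draw(0.5, c(1, 1, 1), c(1, 1, 1))
  ppp <- pattern_posterior(perfect)
  expect_equal(ppp$median_prob[ppp$pattern == "111"], 1)

  # uninformative indicators make every pattern an exact 0.5 tie,
  # which the inclusive cut-off labels screening
  tie <- single_draw(0.5, c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  ppt <- pattern_posterior(tie)
  expect_identical(ppt$median_prob, rep(0.5, 8))
  expect_identical(ppt$label, rep("screening", 8))
})

test_that("latent reference labels patients by pattern, deterministically", {
  d <- single_draw(0.5, c(1, 1, 1), c(1, 1, 1))
  ind <- data.frame(patient_id = c("A", "B", "C"),
                    ind1 = c(1, 1, 0), ind2 = c(1, 1, 0), ind3 = c(1, 1, 0))
  lr <- latent_reference(ind, d)
  expect_identical(lr$label, c("screening", "screening", "non-screening"))
  expect_identical(attr(lr, "n_screening"), 2L)
  # identical patterns -> identical labels
  expect_identical(lr$label[1], lr$label[2])
  expect_error(latent_reference(data.frame(patient_id = "A", ind1 = NA,
                                           ind2 = 1, ind3 = 1), d), "missing")
})

test_that("posterior recovers generating parameters at large n", {
  cfg <- synthetic_config(n_patients = 100000, prevalence = 0.45,
                          indicator_sens = c(0.95, 0.8, 0.8),
                          indicator_spec = c(0.95, 0.7, 0.7),
                          feature_probs = list(), seed = 17)
  co <- generate_cohort(cfg)
  d <- gibbs_sample(pattern_counts(co$indicators), seed = 4)
  med <- apply(d$draws, 2, median)
  expect_equal(unname(med["prevalence"]), 0.45, tolerance = 0.02 / 0.45)
  expect_equal(unname(med[c("sens1", "sens2", "sens3")]), c(0.95, 0.8, 0.8),
               tolerance = 0.03)
  expect_equal(unname(med[c("spec1", "spec2", "spec3")]), c(0.95, 0.7, 0.7),
               tolerance = 0.03)
  expect_lt(d$rhat_prevalence, 1.05)
})

test_that("independence and dependence models label patients nearly identically
           when the true within-class dependence is small", {
  cfg <- synthetic_config(n_patients = 1230, dep_cov_pos = 0.02, dep_cov_neg = 0.015,
                          feature_probs = list(), seed = 29)
  co <- generate_cohort(cfg)
  counts <- pattern_counts(co$indicators)
  # full default chains: the dependence posterior mixes more slowly and a
  # short single chain can leave borderline patterns on the wrong side
  lab_ind <- latent_reference(co$indicators, gibbs_sample(counts, seed = 2))
  lab_dep <- latent_reference(co$indicators,
                              gibbs_sample(counts, dependence = TRUE, seed = 2))
  expect_gt(mean(lab_ind$label == lab_dep$label), 0.95)
})
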