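test_that("intercept-only fit matches the closed form", {
  y <- c(rep(1, 30), rep(0, 70))
  f <- data.frame(dummy = rep(0L, 100))
  m <- fit_logistic(f, y, character(0))
  ybar <- 0.3
  expect_equal(unname(m$coefficients), log(ybar / (1 - ybar)), tolerance = 1e-8)
  expect_equal(m$loglik, 100 * (ybar * log(ybar) + 0.7 * log(0.7)), tolerance = 1e-8)
  expect_equal(m$bic, 1 * log(100) - 2 * m$loglik)
})

test_that("single binary predictor recovers the 2x2 log odds ratio", {
  # cells: a = y1x1, b = y1x0, c = y0x1, d = y0x0
  a <- 40; b <- 25; c <- 15; d <- 60
  f <- data.frame(x = c(rep(1L, a + c), rep(0L, b + d)))
  y <- c(rep(1, a), rep(0, c), rep(1, b), rep(0, d))
  m <- fit_logistic(f, y, "x")
  expect_equal(unname(m$coefficients["x"]), log(a * d / (b * c)), tolerance = 1e-8)
  expect_equal(unname(m$coefficients["(Intercept)"]), log(b / d), tolerance = 1e-8)
  expect_true(m$converged)
})

test_that("the lean IRLS agrees with stats::glm on multivariable data", {
  dat <- make_logit_data(500, 6, c(-1.2, 0.8, 0, 0.5, -0.3, 0), intercept = 0.2, seed = 3)
  m <- fit_logistic(dat$features, dat$y, names(dat$features))
  ref <- stats::glm(dat$y ~ ., data = dat$features, family = binomial())
  expect_equal(unname(m$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(m$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_equal(m$bic, BIC(ref), tolerance = 1e-6)
})

test_that("complete separation is flagged and capped, not fatal", {
  f <- data.frame(x = c(rep(1L, 20), rep(0L, 20)))
  y <- f$x
  m <- fit_logistic(f, y, "x")
  expect_false(m$converged)
  expect_true(all(abs(m$coefficients) <= 15))
})

test_that("BIC is internally consistent", {
  dat <- make_logit_data(300, 4, c(-1, 0.5, 0, 0), seed = 5)
  m <- fit_logistic(dat$features, dat$y, c("v1", "v2"))
  expect_equal(m$bic, m$k * log(m$n) - 2 * m$loglik)
  expect_identical(m$k, 3L)
})

test_that("best-subset selects intercept-only when outcome is independent of candidates", {
  set.seed(101)
  n <- 5000
  f <- as.data.frame(matrix(rbinom(n * 8, 1L, 0.4), n, 8,
                            dimnames = list(NULL, paste0("v", 1:8))))
  y <- rbinom(n, 1L, 0.45)
  b <- best_subset_by_bic(f, y, names(f))
  expect_length(b$variables, 0)
})

test_that("best-subset recovers a planted 3-variable truth", {
  dat <- make_logit_data(10000, 10, c(1.5, 0, 0, -1.2, 0, 0, 0, 1.0, 0, 0),
                         intercept = -0.4, seed = 7)
  b <- best_subset_by_bic(dat$features, dat$y, names(dat$features))
  expect_setequal(b$variables, c("v1", "v4", "v8"))
})

test_that("a single strong candidate beats intercept-only by direct BIC comparison", {
  dat <- make_logit_data(2000, 1, 1.8, seed = 11)
  b <- best_subset_by_bic(dat$features, dat$y, "v1")
  m0 <- fit_logistic(dat$features, dat$y, character(0))
  m1 <- fit_logistic(dat$features, dat$y, "v1")
  expect_identical(b$variables, "v1")
  expect_lt(m1$bic, m0$bic)
  expect_equal(b$bic, m1$bic)
})

test_that("predicted probabilities follow the inverse logit", {
  f <- data.frame(x = c(0L, 1L, 1L, 0L))
  m <- fit_logistic(f, c(0, 1, 1, 1), "x")
  m$coefficients[] <- c(0, 0)
  expect_equal(predict_prob(m, f), rep(0.5, 4))
  m$coefficients[] <- c(log(3), 0)
  expect_equal(predict_prob(m, f), rep(0.75, 4))
  m$coefficients[] <- c(0.4, -1.1)  # negative flag coefficient lowers the probability
  p <- predict_prob(m, f)
  expect_true(all(p[f$x == 1] < p[f$x == 0]))
  expect_error(predict_prob(m, data.frame(z = 1)), "x")
})

test_that("AUC equals the brute-force concordant-pair proportion", {
  expect_equal(auc(rep(0.4, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  r <- auc(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0))
  expect_equal(r$auc, 0.75)  # 3 of 4 pairs concordant
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])

  set.seed(23)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    sc <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    lb <- rbinom(n, 1L, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(auc(sc, lb)$auc, brute_force_auc(sc, lb), tolerance = 1e-12)
  }
  expect_error(auc(runif(5), rep(1, 5)), "both classes")
})
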