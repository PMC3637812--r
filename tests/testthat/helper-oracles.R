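# Independent oracles and small fixture builders for the test suite.
# These deliberately avoid the code paths they check.

# Brute-force AUC: proportion of (positive, negative) pairs ranked
# concordantly, ties counting one half.
brute_force_auc <- function(scores, labels01) {
  pos <- scores[labels01 == 1]
  neg <- scores[labels01 == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Brute-force Gini impurity decrease of splitting `idx` rows on binary x.
brute_force_gini_decrease <- function(x, y) {
  gini <- function(v) {
    if (!length(v)) return(0)
    p <- mean(v); 1 - p^2 - (1 - p)^2
  }
  n <- length(y)
  gini(y) - sum(x == 0) / n * gini(y[x == 0]) - sum(x == 1) / n * gini(y[x == 1])
}

# Exact posterior mean of the screening prevalence for the two-cell data
# {111: n111, 000: n000} under the latent class model with beta priors and
# the identifiability constraint S_j + C_j > 1.  Works by binomial
# expansion of the likelihood, after which every term factorizes into a
# prevalence integral (analytic beta moments) times, per indicator, a 2-D
# integral over the truncated (S, C) prior box, evaluated by midpoint
# quadrature.  Independent of the Gibbs sampler.
grid_posterior_mean_prev <- function(n111, n000, priors, grid = 800L) {
  s <- (seq_len(grid) - 0.5) / grid  # shared abscissae for S and C
  # per-indicator truncated integral J_j(k, m) of
  #   S^k (1-S)^m (1-C)^(n111-k) C^(n000-m) dPrior(S) dPrior(C), S + C > 1
  J <- function(j, k, m) {
    wS <- dbeta(s, priors$sens[j, 1], priors$sens[j, 2])
    wC <- dbeta(s, priors$spec[j, 1], priors$spec[j, 2])
    f1 <- s^k * (1 - s)^m * wS
    f2 <- (1 - s)^(n111 - k) * s^(n000 - m) * wC
    # for each S_i sum f2 over C > 1 - S_i: tail sums of f2; the diagonal
    # midpoint cells sit exactly on S + C = 1 and get half weight
    tail2 <- rev(cumsum(rev(f2)))
    idx <- grid - seq_len(grid) + 1L
    sum(f1 * (tail2[idx] - 0.5 * f2[idx])) / grid^2
  }
  lbeta0 <- lbeta(priors$prev[1], priors$prev[2])
  Ipi <- function(e1, e2) exp(lbeta(priors$prev[1] + e1, priors$prev[2] + e2) - lbeta0)
  num <- 0; den <- 0
  for (k in 0:n111) for (m in 0:n000) {
    w <- choose(n111, k) * choose(n000, m)
    Jprod <- prod(vapply(1:3, function(j) J(j, k, m), numeric(1)))
    den <- den + w * Ipi(k + m, n111 + n000 - k - m) * Jprod
    num <- num + w * Ipi(k + m + 1, n111 + n000 - k - m) * Jprod
  }
  num / den
}

# Minimal patient cohort for window/rule tests.
toy_cohort <- function(n, index_date = as.Date("2007-02-15")) {
  data.frame(patient_id = sprintf("T%03d", seq_len(n)),
             age = rep(60L, n), sex = rep("female", n),
             index_date = rep(index_date, n), stringsAsFactors = FALSE)
}

toy_claim <- function(id, date, code, code_system = "ICD-9") {
  data.frame(patient_id = id, date = as.Date(date), code = code,
             code_system = rep_len(code_system, length(id)),
             record_type = rep_len("diagnosis", length(id)),
             stringsAsFactors = FALSE)
}

# Simulated logistic-model data over independent binary flags.
make_logit_data <- function(n, p, beta, intercept = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1L, 0.3), n, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  eta <- intercept + drop(X %*% beta)
  y <- rbinom(n, 1L, plogis(eta))
  list(features = as.data.frame(X), y = y)
}

# Wrap a fixed parameter draw as an lca_draws object (for plug-in tests).
single_draw <- function(prevalence, sens, spec, cov_pos = 0, cov_neg = 0) {
  draws <- matrix(c(prevalence, sens, spec, cov_pos, cov_neg), 1, 9,
                  dimnames = list(NULL, c("prevalence", "sens1", "sens2", "sens3",
                                          "spec1", "spec2", "spec3",
                                          "cov_pos", "cov_neg")))
  structure(list(draws = draws, chain = 1L,
                 mcmc = mcmc_control(1, 2, 0, 1), seed = 0L,
                 dependence = FALSE, rhat_prevalence = NA_real_),
            class = "lca_draws")
}
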