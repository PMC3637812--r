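#' Priors for the latent class model
#'
#' Beta priors for the screening prevalence and for each indicator's
#' sensitivity and specificity. The defaults are the study priors: an
#' informative Beta(10.67, 1.06) on both the sensitivity and the
#' specificity of the endoscopist indication (about 97.5% of its mass on
#' \[0.70, 1\]), flat Beta(1, 1) priors for the two patient indications, and
#' Beta(6, 7.6) on prevalence (95% of its mass on \[0.20, 0.70\]).
#'
#' @param prev Length-2 `c(a, b)` beta parameters for prevalence.
#' @param sens,spec 3x2 matrices of beta parameters, one row per indicator.
#' @return List of class `lca_priors`.
#' @export
lca_priors <- function(prev = c(6, 7.6),
                       sens = rbind(c(10.67, 1.06), c(1, 1), c(1, 1)),
                       spec = rbind(c(10.67, 1.06), c(1, 1), c(1, 1))) {
  sens <- as.matrix(sens); spec <- as.matrix(spec)
  if (length(prev) != 2 || any(prev <= 0)) stop("prevalence beta parameters must be > 0", call. = FALSE)
  if (!all(dim(sens) == c(3, 2)) || !all(dim(spec) == c(3, 2))) {
    stop("'sens' and 'spec' must be 3x2 beta-parameter matrices", call. = FALSE)
  }
  if (any(sens <= 0) || any(spec <= 0)) stop("beta parameters must be > 0", call. = FALSE)
  structure(list(prev = as.numeric(prev), sens = sens, spec = spec),
            class = "lca_priors")
}

#' Latent class model parameters
#'
#' A parameter point of the two-class model: screening prevalence,
#' per-indicator sensitivity and specificity, and optional within-class
#' covariances between indicators 2 and 3 (`cov_pos` among screening,
#' `cov_neg` among non-screening patients). Covariances must lie in the
#' range keeping all within-class joint cell probabilities in \[0, 1\].
#'
#' @param prevalence Probability the latent indication is screening.
#' @param sens,spec Length-3 sensitivities / specificities.
#' @param cov_pos,cov_neg Within-class covariances (0 = conditional
#'   independence).
#' @return List of class `lca_params`.
#' @export
lca_params <- function(prevalence, sens, spec, cov_pos = 0, cov_neg = 0) {
  check_prob(prevalence, "prevalence")
  if (length(sens) != 3 || length(spec) != 3) stop("'sens' and 'spec' must have length 3", call. = FALSE)
  check_prob(sens, "sens"); check_prob(spec, "spec")
  rp <- cov_range(sens[2], sens[3])
  rn <- cov_range(1 - spec[2], 1 - spec[3])
  tol <- 1e-12
  if (cov_pos < rp[1] - tol || cov_pos > rp[2] + tol) {
    stop(sprintf("'cov_pos' outside valid range [%.6f, %.6f]", rp[1], rp[2]), call. = FALSE)
  }
  if (cov_neg < rn[1] - tol || cov_neg > rn[2] + tol) {
    stop(sprintf("'cov_neg' outside valid range [%.6f, %.6f]", rn[1], rn[2]), call. = FALSE)
  }
  structure(list(prevalence = prevalence, sens = as.numeric(sens),
                 spec = as.numeric(spec), cov_pos = cov_pos, cov_neg = cov_neg),
            class = "lca_params")
}

# Unconditional mixture components over the 8 patterns:
#   p1[t] = pi * P(pattern t | screening), p0[t] = (1-pi) * P(t | non-screening).
# Indicator 1 enters independently; indicators 2 and 3 through the
# covariance-adjusted within-class joint.
pattern_components <- function(params) {
  pm <- pattern_matrix()
  S <- params$sens; C <- params$spec
  q1 <- joint23(S[2], S[3], params$cov_pos)
  q0 <- joint23(1 - C[2], 1 - C[3], params$cov_neg)
  idx <- cell23_index(pm[, "t2"], pm[, "t3"])
  a1 <- ifelse(pm[, "t1"] == 1L, S[1], 1 - S[1]) * q1[idx]
  a0 <- ifelse(pm[, "t1"] == 1L, 1 - C[1], C[1]) * q0[idx]
  list(p1 = params$prevalence * a1, p0 = (1 - params$prevalence) * a0)
}

#' Pattern cell probabilities under the latent class model
#'
#' `cell_probability()` returns the marginal probability of one indicator
#' response pattern; `cell_probabilities()` returns all 8 (they sum to 1
#' for any valid parameter point).
#'
#' @param pattern Length-3 binary vector `(t1, t2, t3)` or a string such as
#'   `"101"`.
#' @param params An [lca_params()].
#' @return Probability (or named length-8 vector).
#' @export
cell_probability <- function(pattern, params) {
  if (is.character(pattern)) pattern <- as.integer(strsplit(pattern, "")[[1]])
  if (length(pattern) != 3 || !all(pattern %in% c(0, 1))) {
    stop("'pattern' must be three binary values", call. = FALSE)
  }
  cell_probabilities(params)[[paste(pattern, collapse = "")]]
}

#' @rdname cell_probability
#' @export
cell_probabilities <- function(params) {
  stopifnot(inherits(params, "lca_params"))
  comp <- pattern_components(params)
  stats::setNames(comp$p1 + comp$p0, PATTERN_LEVELS)
}

#' Multinomial log likelihood of pattern counts
#'
#' @param counts Named count vector over the 8 patterns, as from
#'   [pattern_counts()].
#' @param params An [lca_params()].
#' @return Log likelihood; `-Inf` (with a warning) if an observed cell has
#'   probability zero.
#' @export
log_likelihood <- function(counts, params) {
  counts <- check_counts(counts)
  p <- cell_probabilities(params)
  if (any(counts > 0 & p == 0)) {
    warning("observed pattern with zero model probability; log likelihood is -Inf")
    return(-Inf)
  }
  sum(counts[counts > 0] * log(p[counts > 0]))
}

check_counts <- function(counts) {
  if (!is.null(names(counts))) {
    if (!setequal(names(counts), PATTERN_LEVELS)) {
      stop("counts must be named by the 8 patterns 000..111", call. = FALSE)
    }
    counts <- counts[PATTERN_LEVELS]
  } else if (length(counts) == 8) {
    names(counts) <- PATTERN_LEVELS
  } else {
    stop("counts must have length 8", call. = FALSE)
  }
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative", call. = FALSE)
  counts
}

#' Beta prior interval coverage
#'
#' Probability a Beta(a, b) variable falls in `lo <= x <= hi`, via the
#' regularized incomplete beta function. Used to verify elicited priors
#' against their stated coverage (e.g. Beta(10.67, 1.06) on \[0.70, 1\],
#' Beta(6, 7.6) on \[0.20, 0.70\]).
#'
#' @param a,b Beta shape parameters (> 0).
#' @param lo,hi Interval bounds, `0 <= lo < hi <= 1`.
#' @return Coverage probability.
#' @export
prior_coverage <- function(a, b, lo, hi) {
  if (a <= 0 || b <= 0) stop("beta parameters must be > 0", call. = FALSE)
  if (lo < 0 || hi > 1 || lo >= hi) stop("require 0 <= lo < hi <= 1", call. = FALSE)
  stats::pbeta(hi, a, b) - stats::pbeta(lo, a, b)
}

#' MCMC settings for the Gibbs sampler
#'
#' @param chains Number of chains.
#' @param iter Iterations per chain.
#' @param burnin Discarded initial iterations per chain.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @export
mcmc_control <- function(chains = 3L, iter = 20000L, burnin = 5000L, thin = 5L) {
  stopifnot(chains >= 1, iter > burnin, burnin >= 0, thin >= 1)
  list(chains = as.integer(chains), iter = as.integer(iter),
       burnin = as.integer(burnin), thin = as.integer(thin))
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Gibbs sampler for the Bayesian latent class model
#'
#' Data-augmentation Gibbs sampling of the two-class model from the 8
#' pattern counts. Each sweep (i) splits every pattern count into latent
#' screening / non-screening counts by a binomial draw with the current
#' class posterior, then (ii) updates prevalence and indicator 1's
#' sensitivity/specificity by conjugate beta draws. Under conditional
#' independence (`dependence = FALSE`) indicators 2 and 3 also get
#' conjugate beta updates; under the dependence model their within-class
#' (t2, t3) cell probabilities get conjugate Dirichlet(1,1,1,1) updates,
#' from which sensitivity, specificity and the within-class covariances
#' are derived. Label switching is excluded by rejecting draws with
#' `S_j + C_j <= 1` (each indicator must be better than label-inverted
#' guessing); the unconstrained likelihood is invariant under
#' `(pi, S, C) -> (1 - pi, 1 - C, 1 - S)`.
#'
#' A split-chain potential scale reduction factor on prevalence is
#' reported; values above the threshold raise a warning, not an error.
#'
#' @param counts Pattern counts from [pattern_counts()].
#' @param priors An [lca_priors()].
#' @param mcmc An [mcmc_control()].
#' @param dependence Fit the within-class dependence model for indicators
#'   2 and 3?
#' @param seed Integer seed (chain c uses `seed + c - 1`).
#' @param rhat_warn Warn if split-chain Rhat on prevalence exceeds this.
#' @return Object of class `lca_draws`: matrix `draws` (columns
#'   `prevalence`, `sens1..3`, `spec1..3`, `cov_pos`, `cov_neg`), `chain`
#'   ids, the settings, and `rhat_prevalence`.
#' @export
gibbs_sample <- function(counts, priors = lca_priors(), mcmc = mcmc_control(),
                         dependence = FALSE, seed = 1L, rhat_warn = 1.05) {
  counts <- check_counts(counts)
  stopifnot(inherits(priors, "lca_priors"))
  pm <- pattern_matrix()
  t1 <- pm[, "t1"]; idx23 <- cell23_index(pm[, "t2"], pm[, "t3"])
  cell_of <- lapply(1:4, function(j) which(idx23 == j))
  N <- sum(counts)
  n_keep <- (mcmc$iter - mcmc$burnin) %/% mcmc$thin
  par_names <- c("prevalence", "sens1", "sens2", "sens3",
                 "spec1", "spec2", "spec3", "cov_pos", "cov_neg")

  draw_pair <- function(aS, bS, aC, bC, s1, s0, c1, c0, prev_S, prev_C) {
    # conjugate beta update with rejection enforcing S + C > 1
    for (i in 1:10000) {
      S <- stats::rbeta(1, aS + s1, bS + s0)
      C <- stats::rbeta(1, aC + c1, bC + c0)
      if (S + C > 1) return(c(S, C))
    }
    c(prev_S, prev_C)  # pathological corner; keep current state
  }

  all_draws <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    set.seed(seed + ch - 1L)
    # initial values from the priors, respecting the constraint
    prev <- stats::rbeta(1, priors$prev[1], priors$prev[2])
    S <- numeric(3); C <- numeric(3)
    for (j in 1:3) {
      sc <- draw_pair(priors$sens[j, 1], priors$sens[j, 2],
                      priors$spec[j, 1], priors$spec[j, 2],
                      0, 0, 0, 0, 0.8, 0.8)
      S[j] <- sc[1]; C[j] <- sc[2]
    }
    cov_pos <- 0; cov_neg <- 0
    out <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
    kept <- 0L
    for (it in seq_len(mcmc$iter)) {
      comp <- pattern_components(lca_params(prev, S, C, cov_pos, cov_neg))
      tot <- comp$p1 + comp$p0
      theta <- ifelse(tot > 0, comp$p1 / tot, 0.5)
      y <- stats::rbinom(8L, counts, theta)   # latent screening count per cell
      npos <- sum(y); z <- counts - y
      prev <- stats::rbeta(1, priors$prev[1] + npos, priors$prev[2] + N - npos)
      # indicator 1: plain conjugate update
      sc <- draw_pair(priors$sens[1, 1], priors$sens[1, 2],
                      priors$spec[1, 1], priors$spec[1, 2],
                      sum(y * t1), npos - sum(y * t1),
                      sum(z * (1 - t1)), sum(z * t1), S[1], C[1])
      S[1] <- sc[1]; C[1] <- sc[2]
      if (!dependence) {
        for (j in 2:3) {
          tj <- pm[, j]
          sc <- draw_pair(priors$sens[j, 1], priors$sens[j, 2],
                          priors$spec[j, 1], priors$spec[j, 2],
                          sum(y * tj), npos - sum(y * tj),
                          sum(z * (1 - tj)), sum(z * tj), S[j], C[j])
          S[j] <- sc[1]; C[j] <- sc[2]
        }
      } else {
        n1 <- vapply(cell_of, function(ix) sum(y[ix]), numeric(1))
        n0 <- vapply(cell_of, function(ix) sum(z[ix]), numeric(1))
        ok <- FALSE
        for (i in 1:10000) {
          th1 <- rdirichlet1(1 + n1)   # screening-class (t2,t3) cells
          th0 <- rdirichlet1(1 + n0)   # non-screening-class cells
          S2 <- th1[3] + th1[4]; S3 <- th1[2] + th1[4]
          C2 <- th0[1] + th0[2]; C3 <- th0[1] + th0[3]
          if (S2 + C2 > 1 && S3 + C3 > 1) { ok <- TRUE; break }
        }
        if (ok) {
          S[2] <- S2; S[3] <- S3; C[2] <- C2; C[3] <- C3
          cov_pos <- th1[4] - S2 * S3
          cov_neg <- th0[1] - C2 * C3
        }
      }
      if (it > mcmc$burnin && (it - mcmc$burnin) %% mcmc$thin == 0L) {
        kept <- kept + 1L
        out[kept, ] <- c(prev, S, C, cov_pos, cov_neg)
      }
    }
    all_draws[[ch]] <- out
  }
  draws <- do.call(rbind, all_draws)
  chain <- rep(seq_len(mcmc$chains), each = n_keep)
  rhat <- split_rhat(draws[, "prevalence"], chain)
  if (is.finite(rhat) && rhat > rhat_warn) {
    warning(sprintf("split-chain Rhat on prevalence = %.3f exceeds %.2f; chains may not have converged",
                    rhat, rhat_warn))
  }
  structure(list(draws = draws, chain = chain, mcmc = mcmc, seed = seed,
                 dependence = dependence, priors = priors, counts = counts,
                 rhat_prevalence = rhat),
            class = "lca_draws")
}

# Split-chain potential scale reduction factor (each chain halved).
split_rhat <- function(x, chain) {
  pieces <- list()
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    h <- length(v) %/% 2
    if (h < 2) return(NA_real_)
    pieces <- c(pieces, list(v[1:h], v[(h + 1):(2 * h)]))
  }
  m <- length(pieces); n <- length(pieces[[1]])
  means <- vapply(pieces, mean, numeric(1))
  vars <- vapply(pieces, stats::var, numeric(1))
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior summaries of the latent class parameters
#'
#' Posterior median and central 95% credible interval for every parameter.
#'
#' @param draws An `lca_draws` object.
#' @return Data frame with columns `parameter`, `median`, `lower`, `upper`.
#' @export
posterior_summary <- function(draws) {
  stopifnot(inherits(draws, "lca_draws"))
  q <- apply(draws$draws, 2, stats::quantile, probs = c(0.5, 0.025, 0.975))
  data.frame(parameter = colnames(draws$draws),
             median = q[1, ], lower = q[2, ], upper = q[3, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Posterior screening probability per indicator pattern
#'
#' For every retained draw and every pattern, computes
#' `P(screening | pattern) = p1 / (p1 + p0)` from the draw's parameters,
#' then summarises each pattern by the posterior median and dichotomizes at
#' 50% (median exactly 0.5 labels screening).
#'
#' @param draws An `lca_draws` object.
#' @return Data frame: `pattern`, `t1`, `t2`, `t3`, `median_prob`, `label`.
#' @export
pattern_posterior <- function(draws) {
  stopifnot(inherits(draws, "lca_draws"))
  d <- draws$draws
  if (nrow(d) < 1) stop("no retained draws", call. = FALSE)
  pm <- pattern_matrix()
  q1cells <- cbind(joint23_mat(d[, "sens2"], d[, "sens3"], d[, "cov_pos"]))
  q0cells <- cbind(joint23_mat(1 - d[, "spec2"], 1 - d[, "spec3"], d[, "cov_neg"]))
  med <- numeric(8)
  for (k in 1:8) {
    t1 <- pm[k, "t1"]; ix <- cell23_index(pm[k, "t2"], pm[k, "t3"])
    a1 <- ifelse(t1 == 1L, d[, "sens1"], 1 - d[, "sens1"]) * q1cells[, ix]
    a0 <- ifelse(t1 == 1L, 1 - d[, "spec1"], d[, "spec1"]) * q0cells[, ix]
    p1 <- d[, "prevalence"] * a1
    p0 <- (1 - d[, "prevalence"]) * a0
    med[k] <- stats::median(p1 / (p1 + p0))
  }
  data.frame(pattern = PATTERN_LEVELS,
             t1 = pm[, "t1"], t2 = pm[, "t2"], t3 = pm[, "t3"],
             median_prob = med,
             label = label_string(as.integer(med >= 0.5)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# joint23 vectorized over draws: returns n x 4 matrix.
joint23_mat <- function(p2, p3, cov) {
  cbind((1 - p2) * (1 - p3) + cov,
        (1 - p2) * p3 - cov,
        p2 * (1 - p3) - cov,
        p2 * p3 + cov)
}

#' Latent reference standard labels
#'
#' Assigns every patient the dichotomized posterior label of their
#' indicator pattern; patients with identical patterns always receive
#' identical labels.
#'
#' @param indicators Indicator table (`patient_id`, `ind1..ind3`, no
#'   missing values).
#' @param draws An `lca_draws` object.
#' @return Data frame `patient_id`, `pattern`, `prob`, `label`; the number
#'   of screening labels is attached as attribute `n_screening`.
#' @export
latent_reference <- function(indicators, draws) {
  pp <- pattern_posterior(draws)
  m <- as.matrix(indicators[c("ind1", "ind2", "ind3")])
  if (anyNA(m)) stop("missing indicator values", call. = FALSE)
  pat <- paste0(m[, 1], m[, 2], m[, 3])
  ix <- match(pat, pp$pattern)
  out <- data.frame(patient_id = indicators$patient_id, pattern = pat,
                    prob = pp$median_prob[ix], label = pp$label[ix],
                    stringsAsFactors = FALSE)
  attr(out, "n_screening") <- sum(out$label == "screening")
  out
}
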