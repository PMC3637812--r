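# Model-based classifiers: logistic regression with exhaustive BIC
# best-subset selection, and ROC/AUC scoring.

# Build the design matrix for a variable list: intercept, numeric age,
# sex as a male dummy, binary flags as-is.
build_design <- function(features, variables) {
  n <- nrow(features)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (v in variables) {
    if (!v %in% names(features)) stop(sprintf("variable '%s' not found in features", v), call. = FALSE)
    col <- features[[v]]
    if (v == "sex" || is.character(col) || is.factor(col)) {
      col <- as.integer(as.character(col) == "male")
    }
    if (anyNA(col)) stop(sprintf("variable '%s' has missing values", v), call. = FALSE)
    X <- cbind(X, as.numeric(col))
    colnames(X)[ncol(X)] <- v
  }
  X
}

# Aggregate Bernoulli rows sharing a covariate pattern into binomial
# groups; IRLS then runs on the (much smaller) grouped data.
aggregate_design <- function(X, y) {
  key <- do.call(paste, c(as.data.frame(X), list(sep = "\r")))
  s <- rowsum(y, key, reorder = FALSE)
  n <- rowsum(rep(1, length(y)), key, reorder = FALSE)
  Xu <- X[!duplicated(key), , drop = FALSE]
  list(X = Xu, s = as.numeric(s), n = as.numeric(n))
}

# Bernoulli log likelihood of grouped fits.
grouped_loglik <- function(mu, s, n) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  sum(s * log(mu) + (n - s) * log(1 - mu))
}

# IRLS (Fisher scoring) on grouped binomial data.  A lean inner loop: the
# exhaustive subset search fits 2^p models, so per-fit overhead matters.
# Agrees with stats::glm.fit to ~1e-7 (checked in the test suite).
irls_fit <- function(X, s, n, maxit = 30L, tol = 1e-9) {
  beta <- numeric(ncol(X))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(n * mu * (1 - mu), 1e-10)
    z <- eta + (s - n * mu) / w
    Xw <- X * w
    nb <- drop(solve(crossprod(Xw, X), crossprod(Xw, z)))  # singular -> error
    if (max(abs(nb - beta)) < tol) { beta <- nb; converged <- TRUE; break }
    if (any(abs(nb) > 30)) { beta <- nb; break }  # diverging: separation
    beta <- nb
  }
  list(coefficients = beta, converged = converged)
}

fit_logistic_grouped <- function(Xu, s, n, n_total, variables) {
  fit <- irls_fit(Xu, s, n)
  coef <- fit$coefficients
  converged <- fit$converged && all(is.finite(coef)) && max(abs(coef)) <= 15
  if (!all(is.finite(coef))) coef[!is.finite(coef)] <- 0
  if (!converged) coef <- pmin(pmax(coef, -15), 15)  # separation guard
  mu <- stats::plogis(drop(Xu %*% coef))
  ll <- grouped_loglik(mu, s, n)
  k <- length(coef)
  structure(list(variables = variables, coefficients = coef,
                 loglik = ll, n = n_total, k = k,
                 bic = k * log(n_total) - 2 * ll,
                 converged = converged),
            class = "screenlca_logit")
}

#' Fit a logistic regression for the screening indication
#'
#' Maximum-likelihood logistic regression (binomial iteratively reweighted
#' least squares) of a binary screening outcome on a set of
#' predictors. Rows sharing a covariate pattern are aggregated into
#' binomial groups first, which leaves the fit unchanged but makes the
#' exhaustive subset search fast. Complete separation is flagged: the
#' model is marked non-converged and its coefficients capped at +/-15.
#'
#' @param features Feature table from [extract_features()] (or any data
#'   frame holding the named variables; `sex` is coded as a male dummy).
#' @param outcome Binary outcome: 0/1, logical, or
#'   "screening"/"non-screening".
#' @param variables Character vector of predictor names (intercept always
#'   included; `character(0)` fits intercept only).
#' @return Object of class `screenlca_logit` with elements `variables`,
#'   `coefficients`, `loglik`, `n`, `k`, `bic`
#'   (`k*log(n) - 2*loglik`), `converged`.
#' @export
fit_logistic <- function(features, outcome, variables) {
  y <- as_binary_label(outcome, "outcome")
  if (length(y) != nrow(features)) stop("outcome length must match features", call. = FALSE)
  X <- build_design(features, variables)
  g <- aggregate_design(X, y)
  fit_logistic_grouped(g$X, g$s, g$n, length(y), variables)
}

#' Exhaustive best-subset selection by BIC
#'
#' Fits all `2^p` subsets of the candidate predictors (intercept always
#' included) and returns the model minimizing BIC. Ties are broken toward
#' fewer variables, then by the candidate order. Any subset whose fit
#' fails is skipped with a warning.
#'
#' @inheritParams fit_logistic
#' @param candidates Candidate predictor names (at most 20).
#' @return The winning `screenlca_logit`, with the BIC table of all
#'   subsets attached as attribute `search` (variables, k, bic).
#' @export
best_subset_by_bic <- function(features, outcome, candidates) {
  p <- length(candidates)
  if (p > 20) stop("at most 20 candidates supported for exhaustive search", call. = FALSE)
  y <- as_binary_label(outcome, "outcome")
  Xfull <- build_design(features, candidates)
  # aggregate once on the full pattern; every sub-design is a column subset
  g <- aggregate_design(Xfull, y)
  n_total <- length(y)
  best <- NULL; best_key <- NULL
  search_bic <- rep(NA_real_, 2^p); search_vars <- character(2^p)
  for (mask in 0:(2^p - 1)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1))) != 0L)
    cols <- c(1L, sel + 1L)
    m <- tryCatch(
      fit_logistic_grouped(g$X[, cols, drop = FALSE], g$s, g$n, n_total,
                           candidates[sel]),
      error = function(e) {
        warning(sprintf("subset {%s} skipped: %s",
                        paste(candidates[sel], collapse = ","), conditionMessage(e)))
        NULL
      })
    search_bic[mask + 1] <- if (is.null(m)) NA_real_ else m$bic
    search_vars[mask + 1] <- paste(candidates[sel], collapse = "+")
    if (is.null(m)) next
    key <- c(m$bic, length(sel), sel, rep(0, p - length(sel)))
    if (is.null(best) || lex_less(key, best_key)) { best <- m; best_key <- key }
  }
  if (is.null(best)) stop("every candidate subset failed to fit", call. = FALSE)
  attr(best, "search") <- data.frame(variables = search_vars,
                                     bic = search_bic, stringsAsFactors = FALSE)
  best
}

# strict lexicographic comparison with tolerance on the leading BIC entry
lex_less <- function(a, b) {
  if (abs(a[1] - b[1]) > 1e-9) return(a[1] < b[1])
  for (i in 2:length(a)) {
    if (a[i] != b[i]) return(a[i] < b[i])
  }
  FALSE
}

#' Predicted screening probabilities from a logistic model
#'
#' @param model A `screenlca_logit`.
#' @param features Feature table containing every model variable.
#' @return Numeric vector of inverse-logit probabilities in (0, 1).
#' @export
predict_prob <- function(model, features) {
  stopifnot(inherits(model, "screenlca_logit"))
  X <- build_design(features, model$variables)
  stats::plogis(drop(X %*% model$coefficients))
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC as the Mann-Whitney concordance probability (ties count 1/2),
#' with a 95% CI by DeLong's method, computed via pROC. Requires both
#' classes present.
#'
#' @param scores Numeric scores (higher = more screening-like).
#' @param labels Binary labels (1/"screening" = positive).
#' @return Object of class `screenlca_roc`: `auc`, `ci` (length 2,
#'   truncated to \[0, 1\]), `n_pos`, `n_neg`.
#' @export
auc <- function(scores, labels) {
  y <- as_binary_label(labels, "labels")
  if (length(unique(y)) < 2) stop("both classes must be present to compute AUC", call. = FALSE)
  r <- pROC::roc(response = y, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  a <- as.numeric(pROC::auc(r))
  ci <- suppressWarnings(tryCatch(
    as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)],
    error = function(e) c(a, a)))
  if (anyNA(ci)) ci <- c(a, a)
  ci <- pmin(pmax(ci, 0), 1)
  ci <- c(min(ci[1], a), max(ci[2], a))
  structure(list(auc = a, ci = ci, n_pos = sum(y == 1), n_neg = sum(y == 0)),
            class = "screenlca_roc")
}

#' @export
print.screenlca_logit <- function(x, ...) {
  cat(sprintf("Logistic model (%s): %d obs, BIC %.2f%s\n",
              if (length(x$variables)) paste(x$variables, collapse = " + ") else "intercept only",
              x$n, x$bic, if (x$converged) "" else " [NOT CONVERGED]"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
print.screenlca_roc <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f); %d positives / %d negatives\n",
              x$auc, x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  invisible(x)
}
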