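# Agreement and accuracy statistics: confusion tables, sensitivity /
# specificity / PPV / NPV with confidence intervals, and Cohen's kappa.

align_labels <- function(pred, ref) {
  if (is.data.frame(pred) || is.data.frame(ref)) {
    if (!is.data.frame(pred) || !is.data.frame(ref) ||
        !all(c("patient_id", "label") %in% names(pred)) ||
        !all(c("patient_id", "label") %in% names(ref))) {
      stop("label tables must both be data frames with patient_id and label",
           call. = FALSE)
    }
    if (!setequal(pred$patient_id, ref$patient_id) ||
        anyDuplicated(pred$patient_id) || anyDuplicated(ref$patient_id)) {
      stop("patient sets of the two label tables do not match", call. = FALSE)
    }
    ref <- ref[match(pred$patient_id, ref$patient_id), ]
    pred <- pred$label; ref <- ref$label
  }
  if (length(pred) != length(ref)) stop("label vectors differ in length", call. = FALSE)
  list(pred = as_binary_label(pred, "pred"), ref = as_binary_label(ref, "ref"))
}

#' Cross-tabulate predicted against reference labels
#'
#' "Screening" is the positive class. Inputs may be label vectors in the
#' same patient order, or data frames with `patient_id` and `label`
#' columns (aligned by id; mismatched patient sets error).
#'
#' @param pred,ref Predicted and reference labels.
#' @return Object of class `confusion_table` with counts `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion <- function(pred, ref) {
  al <- align_labels(pred, ref)
  confusion_table(tp = sum(al$pred == 1 & al$ref == 1),
                  fp = sum(al$pred == 1 & al$ref == 0),
                  fn = sum(al$pred == 0 & al$ref == 1),
                  tn = sum(al$pred == 0 & al$ref == 0))
}

#' @rdname confusion
#' @param tp,fp,fn,tn Cell counts (non-negative).
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || anyNA(counts)) stop("confusion counts must be non-negative", call. = FALSE)
  structure(as.list(counts), class = "confusion_table")
}

prop_ci <- function(x, n, method) {
  if (n == 0) return(c(est = NA_real_, lower = NA_real_, upper = NA_real_))
  p <- x / n
  if (method == "wald") {
    half <- 1.96 * sqrt(p * (1 - p) / n)
    ci <- c(p - half, p + half)
  } else {  # Wilson score
    z <- 1.96
    mid <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    ci <- c(mid - half, mid + half)
  }
  c(est = 100 * p, lower = max(0, 100 * ci[1]), upper = min(100, 100 * ci[2]))
}

#' Accuracy metrics with 95% confidence intervals
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`
#' and NPV `tn/(tn+fn)` as percentages, each with a 95% CI (Wald normal
#' approximation by default, which reproduces the published intervals;
#' Wilson score intervals by option). A metric with a zero denominator is
#' reported as `NA` (undefined), not 0. CIs are truncated to \[0, 100\].
#'
#' @param ct A `confusion_table`.
#' @param ci_method `"wald"` or `"wilson"`.
#' @return Object of class `accuracy_report`: data frame with `metric`,
#'   `estimate`, `lower`, `upper`, `numerator`, `denominator`.
#' @export
accuracy_report <- function(ct, ci_method = c("wald", "wilson")) {
  stopifnot(inherits(ct, "confusion_table"))
  ci_method <- match.arg(ci_method)
  rows <- list(
    sensitivity = c(ct$tp, ct$tp + ct$fn),
    specificity = c(ct$tn, ct$tn + ct$fp),
    ppv = c(ct$tp, ct$tp + ct$fp),
    npv = c(ct$tn, ct$tn + ct$fn)
  )
  out <- do.call(rbind, lapply(names(rows), function(nm) {
    x <- rows[[nm]]
    ci <- prop_ci(x[1], x[2], ci_method)
    data.frame(metric = nm, estimate = ci["est"], lower = ci["lower"],
               upper = ci["upper"], numerator = x[1], denominator = x[2],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(out, class = c("accuracy_report", "data.frame"))
}

#' Cohen's kappa with asymptotic confidence interval
#'
#' Chance-corrected agreement `kappa = (Po - Pe) / (1 - Pe)` between two
#' binary raters, with the large-sample (Fleiss-Cohen-Everitt) standard
#' error for the 95% CI. Undefined (error) when both raters are constant
#' (`Pe = 1`).
#'
#' @param a,b Label vectors or data frames as in [confusion()].
#' @return Object of class `kappa_result`: `kappa`, `ci`, `po`, `pe`, `n`.
#' @export
cohens_kappa <- function(a, b) {
  al <- align_labels(a, b)
  n <- length(al$pred)
  tab <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    tab[i, j] <- sum(al$pred == (i - 1) & al$ref == (j - 1))
  }
  p <- tab / n
  po <- sum(diag(p))
  rowm <- rowSums(p); colm <- colSums(p)
  pe <- sum(rowm * colm)
  if (1 - pe < 1e-12) stop("expected agreement is 1 (both raters constant); kappa undefined", call. = FALSE)
  kappa <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt (1969) asymptotic variance of unweighted kappa
  s1 <- sum(vapply(1:2, function(i) {
    p[i, i] * (1 - (rowm[i] + colm[i]) * (1 - kappa))^2
  }, numeric(1)))
  s2 <- (1 - kappa)^2 * sum(vapply(1:2, function(i) {
    sum(vapply(setdiff(1:2, i), function(j) p[i, j] * (colm[i] + rowm[j])^2, numeric(1)))
  }, numeric(1)))
  s3 <- (kappa - pe * (1 - kappa))^2
  se <- sqrt(max(0, (s1 + s2 - s3))) / ((1 - pe) * sqrt(n))
  structure(list(kappa = kappa, ci = c(max(-1, kappa - 1.96 * se),
                                       min(1, kappa + 1.96 * se)),
                 se = se, po = po, pe = pe, n = n),
            class = "kappa_result")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("Confusion table (positive = screening): tp=%d fp=%d fn=%d tn=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa %.3f (95%% CI %.3f-%.3f); Po=%.4f Pe=%.4f n=%d\n",
              x$kappa, x$ci[1], x$ci[2], x$po, x$pe, x$n))
  invisible(x)
}
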