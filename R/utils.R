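# Internal helpers shared across modules.

# The 8 indicator response patterns (t1, t2, t3), in fixed binary order.
PATTERN_LEVELS <- c("000", "001", "010", "011", "100", "101", "110", "111")

pattern_matrix <- function() {
  m <- do.call(rbind, lapply(strsplit(PATTERN_LEVELS, ""), as.integer))
  dimnames(m) <- list(PATTERN_LEVELS, c("t1", "t2", "t3"))
  m
}

# Map (t2, t3) to a cell index 1..4 in order (0,0), (0,1), (1,0), (1,1).
cell23_index <- function(t2, t3) 1L + 2L * t2 + t3

# Joint probability of (t2, t3) within one latent class, given the two
# marginal positive-response probabilities and a within-class covariance.
# Order: (0,0), (0,1), (1,0), (1,1).
joint23 <- function(p2, p3, cov) {
  c((1 - p2) * (1 - p3) + cov,
    (1 - p2) * p3 - cov,
    p2 * (1 - p3) - cov,
    p2 * p3 + cov)
}

# Valid covariance range implied by the marginals (joint cells in [0,1]).
cov_range <- function(p2, p3) {
  c(max(-p2 * p3, -(1 - p2) * (1 - p3)),
    min(p2 * (1 - p3), p3 * (1 - p2)))
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", field), call. = FALSE)
  }
  invisible(x)
}

# Normalize a screening label vector to integer 0/1 (1 = screening).
# Accepts 0/1 numerics, logicals, or "screening"/"non-screening" strings.
as_binary_label <- function(x, field = "label") {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    bad <- !x %in% c("screening", "non-screening")
    if (any(bad)) {
      stop(sprintf("'%s' contains values other than screening/non-screening", field),
           call. = FALSE)
    }
    return(as.integer(x == "screening"))
  }
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    if (anyNA(x) || !all(x %in% c(0, 1))) {
      stop(sprintf("'%s' must be binary 0/1 without missing values", field),
           call. = FALSE)
    }
    return(as.integer(x))
  }
  stop(sprintf("cannot interpret '%s' as a binary screening label", field),
       call. = FALSE)
}

label_string <- function(x01) ifelse(x01 == 1L, "screening", "non-screening")
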