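#' Synthetic colonoscopy cohort configuration
#'
#' Assembles and validates the parameters of the synthetic cohort generator:
#' a latent screening indication with prevalence `prevalence`, three
#' imperfect binary indication indicators with per-indicator sensitivity and
#' specificity (indicators 2 and 3 optionally correlated within each latent
#' class), and per-category probabilities of carrying a claims history flag
#' given the latent class.
#'
#' The bundled default configuration (`default_synthetic_config()`) emulates
#' the published study cohort: about 1,230 patients aged 50-75, screening
#' prevalence 0.46, indicator marginals near 46.8/51.0/38.9% screening, and
#' claims-flag marginal frequencies matching the published frequency table,
#' with all flags more common before non-screening exams.
#'
#' @param n_patients Cohort size (>= 1).
#' @param prevalence Probability that the latent indication is screening.
#' @param indicator_sens,indicator_spec Length-3 sensitivity and specificity
#'   of the three indicators (endoscopist, patient indication 1, patient
#'   indication 2), as probabilities of agreeing with the latent class.
#' @param dep_cov_pos,dep_cov_neg Within-class covariance between indicators
#'   2 and 3 among latent screening / non-screening patients (0 = class
#'   conditional independence). Must lie in the range implied by the
#'   marginals.
#' @param feature_probs Named list; each element a length-2 numeric
#'   `c(P(flag | screening), P(flag | non-screening))` for one claims
#'   predictor category. Names must match the code dictionary categories.
#' @param sex_ratio Probability that a patient is male.
#' @param age_range Length-2 integer eligibility bounds in years.
#' @param age_mean,age_sd Mean and SD of the age distribution (normal,
#'   truncated to `age_range`).
#' @param index_period Length-2 `Date` (or ISO-8601 strings): the window the
#'   index colonoscopy dates are drawn from.
#' @param seed Integer seed; generation is fully reproducible given it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 1230L,
                             prevalence = 0.46,
                             indicator_sens = c(0.93, 0.87, 0.72),
                             indicator_spec = c(0.93, 0.80, 0.89),
                             dep_cov_pos = 0,
                             dep_cov_neg = 0,
                             feature_probs = default_feature_probs(),
                             sex_ratio = 0.485,
                             age_range = c(50L, 75L),
                             age_mean = 60.1,
                             age_sd = 6.9,
                             index_period = as.Date(c("2007-01-01", "2007-03-31")),
                             seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1) {
    stop("'n_patients' must be a single count >= 1", call. = FALSE)
  }
  check_prob(prevalence, "prevalence")
  if (length(indicator_sens) != 3 || length(indicator_spec) != 3) {
    stop("'indicator_sens' and 'indicator_spec' must each have length 3", call. = FALSE)
  }
  check_prob(indicator_sens, "indicator_sens")
  check_prob(indicator_spec, "indicator_spec")
  check_prob(sex_ratio, "sex_ratio")
  rng_pos <- cov_range(indicator_sens[2], indicator_sens[3])
  rng_neg <- cov_range(1 - indicator_spec[2], 1 - indicator_spec[3])
  if (dep_cov_pos < rng_pos[1] || dep_cov_pos > rng_pos[2]) {
    stop(sprintf("'dep_cov_pos' outside valid range [%.4f, %.4f]", rng_pos[1], rng_pos[2]),
         call. = FALSE)
  }
  if (dep_cov_neg < rng_neg[1] || dep_cov_neg > rng_neg[2]) {
    stop(sprintf("'dep_cov_neg' outside valid range [%.4f, %.4f]", rng_neg[1], rng_neg[2]),
         call. = FALSE)
  }
  if (!is.list(feature_probs) ||
      (length(feature_probs) > 0 &&
       (is.null(names(feature_probs)) || any(!nzchar(names(feature_probs)))))) {
    stop("'feature_probs' must be a named list of probability pairs", call. = FALSE)
  }
  for (nm in names(feature_probs)) {
    p <- feature_probs[[nm]]
    if (length(p) != 2) {
      stop(sprintf("feature_probs entry '%s' must have two probabilities", nm),
           call. = FALSE)
    }
    check_prob(p, paste0("feature_probs$", nm))
  }
  index_period <- as.Date(index_period)
  if (anyNA(index_period) || length(index_period) != 2 || index_period[1] > index_period[2]) {
    stop("'index_period' must be two ordered valid dates", call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients), prevalence = prevalence,
    indicator_sens = indicator_sens, indicator_spec = indicator_spec,
    dep_cov_pos = dep_cov_pos, dep_cov_neg = dep_cov_neg,
    feature_probs = feature_probs, sex_ratio = sex_ratio,
    age_range = as.integer(age_range), age_mean = age_mean, age_sd = age_sd,
    index_period = index_period, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' @rdname synthetic_config
#' @param path Path to a YAML configuration; defaults to the bundled file.
#' @export
read_synthetic_config <- function(path = NULL, seed = 1L) {
  if (is.null(path)) {
    path <- system.file("extdata", "synthetic_default.yaml", package = "screenlca")
  }
  y <- yaml::read_yaml(path)
  synthetic_config(
    n_patients = y$n_patients, prevalence = y$prevalence,
    indicator_sens = as.numeric(y$indicator_sens),
    indicator_spec = as.numeric(y$indicator_spec),
    dep_cov_pos = y$dep_cov_pos %||% 0, dep_cov_neg = y$dep_cov_neg %||% 0,
    feature_probs = lapply(y$feature_probs, as.numeric),
    sex_ratio = y$sex_ratio, age_range = as.integer(y$age_range),
    age_mean = y$age_mean, age_sd = y$age_sd,
    index_period = as.Date(unlist(y$index_period)), seed = seed
  )
}

#' @rdname synthetic_config
#' @export
default_synthetic_config <- function(seed = 1L) read_synthetic_config(NULL, seed = seed)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname synthetic_config
#' @export
default_feature_probs <- function() {
  read_synthetic_config(NULL)$feature_probs
}

#' Generate a synthetic cohort with known latent indication
#'
#' Draws the latent screening indication, the three indicator responses, and
#' a claims history for every patient. Indicator 1 responds independently
#' with its sensitivity/specificity; indicators 2 and 3 are drawn jointly
#' within each latent class from the covariance-adjusted 2x2 cell
#' probabilities, so the generator and the latent class estimator share one
#' dependence definition. Claims are emitted only for flagged categories,
#' with one claim per flag, a code sampled from the category's dictionary
#' entry, and a date uniform in the category's lookback window ending the
#' day before the index date (so window membership is exercised and the
#' feature extractor recovers the injected flags exactly).
#'
#' @param config A [synthetic_config()].
#' @param dict A code dictionary from [load_code_dictionary()]; categories
#'   must cover `config$feature_probs`.
#' @return List of class `synthetic_cohort` with data frames `truth`
#'   (patient_id, latent_indication, age, sex, index_date), `indicators`
#'   (patient_id, ind1..ind3), `claims` (patient_id, date, code,
#'   code_system, record_type), and the injected `flags` matrix.
#' @export
generate_cohort <- function(config, dict = load_code_dictionary()) {
  stopifnot(inherits(config, "synthetic_config"))
  missing_cat <- setdiff(names(config$feature_probs), names(dict$categories))
  if (length(missing_cat)) {
    stop("feature_probs categories missing from code dictionary: ",
         paste(missing_cat, collapse = ", "), call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_patients
  latent <- stats::rbinom(n, 1L, config$prevalence)

  S <- config$indicator_sens; C <- config$indicator_spec
  p_pos <- ifelse(latent == 1L, S[1], 1 - C[1])
  ind1 <- stats::rbinom(n, 1L, p_pos)
  # indicators 2 and 3: joint cells within each class
  q1 <- joint23(S[2], S[3], config$dep_cov_pos)
  q0 <- joint23(1 - C[2], 1 - C[3], config$dep_cov_neg)
  cell <- integer(n)
  cell[latent == 1L] <- sample.int(4L, sum(latent == 1L), replace = TRUE, prob = q1)
  cell[latent == 0L] <- sample.int(4L, sum(latent == 0L), replace = TRUE, prob = q0)
  ind2 <- as.integer(cell %in% c(3L, 4L))
  ind3 <- as.integer(cell %in% c(2L, 4L))

  # truncated-normal ages on the eligibility range, integer years
  lo <- stats::pnorm(config$age_range[1], config$age_mean, config$age_sd)
  hi <- stats::pnorm(config$age_range[2], config$age_mean, config$age_sd)
  age <- round(stats::qnorm(stats::runif(n, lo, hi), config$age_mean, config$age_sd))
  age <- pmin(pmax(age, config$age_range[1]), config$age_range[2])
  sex <- ifelse(stats::rbinom(n, 1L, config$sex_ratio) == 1L, "male", "female")
  span <- as.integer(config$index_period[2] - config$index_period[1])
  index_date <- config$index_period[1] + sample.int(span + 1L, n, replace = TRUE) - 1L

  patient_id <- sprintf("P%05d", seq_len(n))
  truth <- data.frame(patient_id = patient_id, latent_indication = latent,
                      age = as.integer(age), sex = sex, index_date = index_date,
                      stringsAsFactors = FALSE)
  indicators <- data.frame(patient_id = patient_id, ind1 = ind1, ind2 = ind2,
                           ind3 = ind3, stringsAsFactors = FALSE)

  cats <- names(config$feature_probs)
  flags <- matrix(0L, n, length(cats), dimnames = list(patient_id, cats))
  claim_list <- vector("list", length(cats))
  for (k in seq_along(cats)) {
    cat_nm <- cats[k]
    pr <- config$feature_probs[[cat_nm]]
    p <- ifelse(latent == 1L, pr[1], pr[2])
    fl <- stats::rbinom(n, 1L, p)
    flags[, k] <- fl
    who <- which(fl == 1L)
    if (!length(who)) next
    entry <- dict$categories[[cat_nm]]
    pick <- sample.int(nrow(entry$codes), length(who), replace = TRUE)
    offset <- sample.int(entry$lookback_days, length(who), replace = TRUE) # 1..lookback days before index
    claim_list[[k]] <- data.frame(
      patient_id = patient_id[who],
      date = index_date[who] - offset,
      code = entry$codes$code[pick],
      code_system = entry$codes$code_system[pick],
      record_type = entry$record_type,
      stringsAsFactors = FALSE
    )
  }
  claims <- do.call(rbind, claim_list[!vapply(claim_list, is.null, logical(1))])
  if (is.null(claims)) {
    claims <- data.frame(patient_id = character(), date = as.Date(character()),
                         code = character(), code_system = character(),
                         record_type = character(), stringsAsFactors = FALSE)
  } else {
    claims <- claims[order(claims$patient_id, claims$date, claims$code), , drop = FALSE]
    rownames(claims) <- NULL
  }
  structure(list(truth = truth, indicators = indicators, claims = claims,
                 flags = flags, config = config),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to delimited files
#'
#' Writes `truth.csv`, `indicators.csv` and `claims.csv` (comma-separated,
#' header row, ISO-8601 dates) into `dir`. Output is byte-identical for
#' identical seeds.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("truth.csv", "indicators.csv", "claims.csv"))
  utils::write.csv(cohort$truth, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$indicators, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$claims, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Tabulate indicator response patterns
#'
#' Counts the 8 possible response patterns (t1, t2, t3) of the three
#' indication indicators; this is the sufficient statistic of the latent
#' class likelihood.
#'
#' @param indicators Data frame with columns `ind1`, `ind2`, `ind3` (binary,
#'   1 = screening) and optionally `patient_id` (used in error messages).
#' @return Named integer vector over patterns `"000"` to `"111"`
#'   (order t1, t2, t3), summing to `nrow(indicators)`.
#' @export
pattern_counts <- function(indicators) {
  need <- c("ind1", "ind2", "ind3")
  if (!all(need %in% names(indicators))) {
    stop("'indicators' must have columns ind1, ind2, ind3", call. = FALSE)
  }
  m <- as.matrix(indicators[need])
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)
    ids <- if ("patient_id" %in% names(indicators)) {
      indicators$patient_id[bad]
    } else bad
    stop("missing indicator values for: ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  if (!all(m %in% c(0, 1))) stop("indicator values must be 0/1", call. = FALSE)
  pat <- paste0(m[, 1], m[, 2], m[, 3])
  counts <- table(factor(pat, levels = PATTERN_LEVELS))
  stats::setNames(as.integer(counts), PATTERN_LEVELS)
}
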