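#' Load a claims code dictionary
#'
#' Reads the category -> code-set mapping used to turn raw claims into
#' binary predictors. Each category carries a record type, a lookback
#' window in days, and a set of (code_system, code) pairs. The bundled
#' dictionary holds the 14 predictor categories (4 prior procedures, 5
#' symptoms, 3 gastrointestinal conditions, large-bowel hospitalization and
#' large-bowel surgery) with synthetic placeholder codes and the standard
#' windows: 4 years (1460 d) for procedures, 1 year (365 d) for symptoms,
#' 5 years (1825 d) for conditions, hospitalizations and surgeries.
#'
#' @param path YAML file; defaults to the bundled dictionary.
#' @return List of class `code_dictionary` with element `categories`.
#' @export
load_code_dictionary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "code_dictionary.yaml", package = "screenlca")
  }
  y <- yaml::read_yaml(path)
  cats <- lapply(y$categories, function(entry) {
    codes <- do.call(rbind, lapply(entry$codes, function(cc) {
      data.frame(code_system = cc$code_system, code = as.character(cc$code),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(codes) || nrow(codes) == 0) stop("empty code set in dictionary", call. = FALSE)
    list(record_type = entry$record_type,
         lookback_days = as.integer(entry$lookback_days),
         codes = codes)
  })
  if (any(vapply(cats, function(x) x$lookback_days <= 0, logical(1)))) {
    stop("lookback_days must be positive", call. = FALSE)
  }
  structure(list(categories = cats, path = path), class = "code_dictionary")
}

#' Lookback window membership
#'
#' A claim counts as history iff it falls in the half-open window
#' `[index_date - lookback_days, index_date)`: the lower bound is included,
#' the index day itself is excluded (a same-day code is taken to be the
#' index exam, not history).
#'
#' @param claim_date,index_date `Date` vectors (recycled).
#' @param lookback_days Positive integer window length.
#' @return Integer 0/1 vector.
#' @export
in_window <- function(claim_date, index_date, lookback_days) {
  claim_date <- as.Date(claim_date)
  index_date <- as.Date(index_date)
  if (anyNA(claim_date) || anyNA(index_date)) {
    stop("unparseable or missing date", call. = FALSE)
  }
  as.integer(claim_date >= index_date - lookback_days & claim_date < index_date)
}

#' Extract binary claims predictors
#'
#' Reduces a claims table to one row per patient: age, sex, and a 0/1 flag
#' per dictionary category, set iff the patient has at least one claim whose
#' (code_system, code) is in the category's code set and whose date lies in
#' the category's lookback window before that patient's index date. The
#' result is deterministic and independent of claim row order.
#'
#' @param claims Data frame with columns `patient_id`, `date`, `code`,
#'   `code_system` (and optionally `record_type`).
#' @param cohort Data frame with `patient_id`, `age`, `sex`, `index_date`;
#'   every claim's patient must appear here.
#' @param dict A [load_code_dictionary()] result.
#' @return Data frame: `patient_id`, `age`, `sex`, then one 0/1 column per
#'   category in dictionary order.
#' @export
extract_features <- function(claims, cohort, dict = load_code_dictionary()) {
  stopifnot(inherits(dict, "code_dictionary"))
  unknown <- setdiff(unique(claims$patient_id), cohort$patient_id)
  if (length(unknown)) {
    stop("claims reference unknown patient ids: ",
         paste(utils::head(unknown, 10), collapse = ", "), call. = FALSE)
  }
  index_date <- as.Date(cohort$index_date)
  if (anyNA(index_date)) stop("unparseable index_date in cohort", call. = FALSE)
  out <- data.frame(patient_id = cohort$patient_id,
                    age = cohort$age, sex = cohort$sex,
                    stringsAsFactors = FALSE)
  cats <- names(dict$categories)
  for (nm in cats) out[[nm]] <- 0L
  if (nrow(claims) == 0) return(out)

  claim_date <- as.Date(claims$date)
  if (anyNA(claim_date)) {
    stop("unparseable claim date at rows: ",
         paste(utils::head(which(is.na(claim_date)), 10), collapse = ", "),
         call. = FALSE)
  }
  row_of <- match(claims$patient_id, cohort$patient_id)
  key <- paste(claims$code_system, claims$code, sep = "\r")
  for (nm in cats) {
    entry <- dict$categories[[nm]]
    ckey <- paste(entry$codes$code_system, entry$codes$code, sep = "\r")
    sel <- key %in% ckey
    if (!any(sel)) next
    hit <- in_window(claim_date[sel], index_date[row_of[sel]], entry$lookback_days) == 1L
    out[[nm]][unique(row_of[sel][hit])] <- 1L
  }
  out
}
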