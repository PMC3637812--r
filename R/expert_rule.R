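#' Load the El-Serag expert rule configuration
#'
#' The expert rule calls a colonoscopy screening iff the patient has (a) no
#' claim matching any of 28 disqualifying symptom/condition categories
#' within each category's lookback window and (b) no prior colonoscopy
#' procedure code in the 4 years before the index exam. The bundled
#' default enumerates 28 named categories with synthetic codes (the
#' original ICD-9 inventory is not public here) and a 4-year diagnosis
#' lookback mirroring the colonoscopy clause.
#'
#' @param path YAML file; defaults to the bundled configuration.
#' @return List of class `elserag_config`.
#' @export
load_elserag_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "elserag.yaml", package = "screenlca")
  }
  y <- yaml::read_yaml(path)
  disq <- lapply(y$disqualifying, function(entry) {
    codes <- do.call(rbind, lapply(entry$codes, function(cc) {
      data.frame(code_system = cc$code_system, code = as.character(cc$code),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(codes) || nrow(codes) == 0) {
      stop("empty code set in El-Serag category ", entry$category, call. = FALSE)
    }
    list(category = entry$category,
         lookback_days = as.integer(entry$lookback_days), codes = codes)
  })
  if (length(disq) != 28) {
    stop(sprintf("El-Serag configuration must list 28 disqualifying categories (got %d)",
                 length(disq)), call. = FALSE)
  }
  col_codes <- do.call(rbind, lapply(y$colonoscopy_codes, function(cc) {
    data.frame(code_system = cc$code_system, code = as.character(cc$code),
               stringsAsFactors = FALSE)
  }))
  if (is.null(col_codes) || nrow(col_codes) == 0) {
    stop("El-Serag configuration has no colonoscopy codes", call. = FALSE)
  }
  structure(list(disqualifying = disq,
                 colonoscopy_codes = col_codes,
                 colonoscopy_lookback_days = as.integer(y$colonoscopy_lookback_days)),
            class = "elserag_config")
}

#' Apply the El-Serag expert rule
#'
#' Absence-based classification: screening iff no disqualifying diagnosis
#' claim in window and no prior colonoscopy claim in the 4-year window.
#' Adding claims can therefore only move a patient from screening to
#' non-screening; a patient with no claims is always screening.
#'
#' @param claims Claims table (`patient_id`, `date`, `code`,
#'   `code_system`).
#' @param cohort Cohort table (`patient_id`, `index_date`).
#' @param config An [load_elserag_config()] result.
#' @return Data frame `patient_id`, `label`.
#' @export
el_serag_classify <- function(claims, cohort, config = load_elserag_config()) {
  stopifnot(inherits(config, "elserag_config"))
  unknown <- setdiff(unique(claims$patient_id), cohort$patient_id)
  if (length(unknown)) {
    stop("claims reference unknown patient ids: ",
         paste(utils::head(unknown, 10), collapse = ", "), call. = FALSE)
  }
  index_date <- as.Date(cohort$index_date)
  disq <- logical(nrow(cohort))
  if (nrow(claims) > 0) {
    claim_date <- as.Date(claims$date)
    if (anyNA(claim_date)) stop("unparseable claim date", call. = FALSE)
    row_of <- match(claims$patient_id, cohort$patient_id)
    key <- paste(claims$code_system, claims$code, sep = "\r")
    hit_category <- function(codes, lookback) {
      ckey <- paste(codes$code_system, codes$code, sep = "\r")
      sel <- key %in% ckey
      if (!any(sel)) return(integer(0))
      inw <- in_window(claim_date[sel], index_date[row_of[sel]], lookback) == 1L
      unique(row_of[sel][inw])
    }
    for (entry in config$disqualifying) {
      disq[hit_category(entry$codes, entry$lookback_days)] <- TRUE
    }
    disq[hit_category(config$colonoscopy_codes, config$colonoscopy_lookback_days)] <- TRUE
  }
  data.frame(patient_id = cohort$patient_id,
             label = label_string(as.integer(!disq)),
             stringsAsFactors = FALSE)
}
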