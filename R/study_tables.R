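#' Published cohort counts
#'
#' Counts transcribed from the published study tables, used to calibrate
#' the synthetic generator and to recompute the study's printed cohort
#' percentages from first principles (count / denominator). All
#' percentages in the publication derive from these counts over the
#' cohort denominators.
#'
#' @return Named list of integer counts: `approached`, `eligible`,
#'   `montreal`, `calgary`, `male`, `endoscopist_screening`,
#'   `patient1_screening`, `patient2_screening`, `latent_screening`,
#'   `elserag_screening`, plus `claims_flags`, a named vector of the 14
#'   claims-category frequencies.
#' @export
published_counts <- function() {
  list(
    approached = 1411L, eligible = 1230L,
    montreal = 689L, calgary = 541L, male = 597L,
    endoscopist_screening = 576L,
    patient1_screening = 627L,
    patient2_screening = 478L,
    latent_screening = 554L,
    elserag_screening = 395L,
    claims_flags = c(
      colonoscopy = 267L, sigmoidoscopy = 76L, polypectomy = 114L,
      dcbe = 65L, rectal_bleeding = 95L, diarrhea = 50L, vomiting = 7L,
      weight_loss = 8L, anemia = 86L, crc = 65L, colorectal_polyps = 205L,
      ibd = 48L, large_bowel_hospitalization = 32L, large_bowel_surgery = 26L
    )
  )
}
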