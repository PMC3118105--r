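# Published summary statistics of the clinical cohort (85 CRPS patients
# with fixed dystonia; 123 affected arms, 114 affected legs) that the
# synthetic-data generator emulates: the posture-combination counts of the
# common arm and leg patterns, the rare-posture counts, the per-patient
# severity mix, and the fraction of patients with bilateral involvement.
# Raw per-patient data are not published; these tabulated counts are the
# only inputs.

#' Observed posture-combination counts
#'
#' The combination patterns of the four common posture indicators and the
#' number of limbs observed with each, as reported for the study cohort.
#' Arms: 118 of 123 affected arms show at least one of finger flexion,
#' wrist flexion, elbow flexion, shoulder adduction.  Legs: 113 of 114
#' affected legs show at least one of toe plantar flexion, ankle plantar
#' flexion/inversion, knee flexion, hip internal rotation.
#'
#' @param limb `"arm"` or `"leg"`.
#' @return a data frame with one logical column per indicator joint and a
#'   `count` column.
#' @export
observed_pattern_counts <- function(limb = c("arm", "leg")) {
  limb <- match.arg(limb)
  if (limb == "arm") {
    tab <- data.frame(
      fingers = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
      wrist = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE),
      elbow = c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
      shoulder = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
      count = c(60L, 20L, 15L, 9L, 4L, 4L, 3L, 1L, 1L, 1L))
  } else {
    tab <- data.frame(
      toes = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
      ankle = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
      knee = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
      hip = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
      count = c(42L, 24L, 17L, 6L, 6L, 6L, 4L, 3L, 3L, 2L))
  }
  tab
}

# rare (non-common-pattern) posture categories and their observed limb
# counts; denominators are all affected limbs (123 arms / 114 legs)
rare_posture_counts <- function(limb) {
  if (limb == "arm") {
    data.frame(joint = c("fingers", "wrist", "elbow"),
               posture = c("extension", "extension", "pronation"),
               count = c(5L, 1L, 3L))
  } else {
    data.frame(joint = c("ankle", "ankle", "ankle", "ankle", "toes", "knee"),
               posture = c("dorsiflexion", "eversion", "dorsiflexion_inversion",
                           "plantar_flexion_eversion", "dorsiflexion",
                           "extension"),
               count = c(2L, 2L, 1L, 2L, 4L, 7L))
  }
}

# observed totals used for default probabilities
OBS_AFFECTED_LIMBS <- c(arm = 123L, leg = 114L)
OBS_COMMON_LIMBS <- c(arm = 118L, leg = 113L)
# both sides affected among patients with that limb type affected
OBS_BILATERAL <- c(arm = 46L, leg = 37L)
OBS_PATIENTS_AFFECTED <- c(arm = 77L, leg = 77L)
# per-patient severity mix of the most affected extremity
OBS_SEVERITY_PROBS <- c(slight = 0.118, mild = 0.412, moderate = 0.247,
                        severe = 0.223)

# one limb row of the cohort schema; joints of the other limb type are NA
blank_limb_row <- function(patient_id, side, limb, severity = "none") {
  row <- as.list(stats::setNames(rep(NA_character_, length(cohort_columns)),
                                 cohort_columns))
  row$patient_id <- patient_id
  row$side <- side
  row$limb <- limb
  for (j in joints_for(limb)) row[[j]] <- "none"
  row$severity <- severity
  row
}

# apply a common-pattern indicator tuple to a blank row
set_common_pattern <- function(row, limb, pattern) {
  ind <- COMMON_INDICATORS[[limb]]
  for (j in names(ind)) {
    if (isTRUE(pattern[[j]]))
      row[[j]] <- strsplit(ind[[j]], "|", fixed = TRUE)[[1]][1]
  }
  row
}

#' Fixture cohort realizing the observed combination table exactly
#'
#' Builds a deterministic cohort with exactly the published count of limbs
#' for each common posture combination (118 arm records in 10 patterns, or
#' 113 leg records in 10 patterns), one limb per synthetic patient with
#' alternating sides and severity `"mild"` throughout.  Running
#' [combination_table()] and [marginal_counts()] on it reproduces the
#' published totals.
#'
#' @param limb `"arm"` or `"leg"`.
#' @return a validated cohort data frame.
#' @export
fixture_cohort <- function(limb = c("arm", "leg")) {
  limb <- match.arg(limb)
  pats <- observed_pattern_counts(limb)
  rows <- list()
  idx <- 0L
  for (i in seq_len(nrow(pats))) {
    for (k in seq_len(pats$count[i])) {
      idx <- idx + 1L
      row <- blank_limb_row(sprintf("%s-%04d", limb, idx),
                            if (idx %% 2L == 0L) "left" else "right",
                            limb, severity = "mild")
      rows[[idx]] <- set_common_pattern(row, limb, pats[i, ])
    }
  }
  cohort <- do.call(rbind, lapply(rows, as.data.frame))
  validate_cohort(cohort)
  cohort
}
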