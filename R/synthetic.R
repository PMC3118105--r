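# Seeded synthetic cohort generator emulating the statistical structure of
# the study cohort: common posture-combination frequencies proportional to
# the observed counts, rare postures at their observed rates, the
# per-patient severity mix, and left/right exchangeability (each side of a
# patient is affected independently with the same probability).

#' Specification of a synthetic cohort
#'
#' @param n_patients number of patients; each contributes two arms and two
#'   legs.
#' @param p_affected named numeric: probability that any single arm / leg is
#'   affected, identical for both sides of a patient (left/right
#'   exchangeability).  Defaults are calibrated so that among patients with
#'   at least one affected limb of the type, the expected share with both
#'   sides affected matches the published bilateral fractions (46/77 arms,
#'   37/77 legs): with side-independence, P(both | >= 1) = q / (2 - q),
#'   giving q = 92/123 for arms and q = 74/114 for legs.
#' @param arm_patterns,leg_patterns data frames of common-pattern indicator
#'   tuples with a `prob` column summing to 1 (see
#'   [observed_pattern_counts()]).
#' @param p_other named numeric: probability that an affected limb carries a
#'   rare (non-common) posture instead of a common pattern (5/123 arms,
#'   1/114 legs).
#' @param arm_rare,leg_rare data frames `joint`, `posture`, `prob` for the
#'   rare categories.
#' @param severity_probs probability of each per-patient maximum severity
#'   grade (slight, mild, moderate, severe).
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the spec including this seed.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        p_affected = c(arm = 92 / 123, leg = 74 / 114),
                        arm_patterns = NULL, leg_patterns = NULL,
                        p_other = c(arm = 5 / 123, leg = 1 / 114),
                        arm_rare = NULL, leg_rare = NULL,
                        severity_probs = OBS_SEVERITY_PROBS,
                        seed = 1L) {
  norm_pat <- function(limb, pats) {
    if (is.null(pats)) {
      pats <- observed_pattern_counts(limb)
      pats$prob <- pats$count / sum(pats$count)
    }
    stopifnot(abs(sum(pats$prob) - 1) < 1e-9)
    pats
  }
  norm_rare <- function(limb, rare) {
    if (is.null(rare)) {
      rare <- rare_posture_counts(limb)
      rare$prob <- rare$count / sum(rare$count)
    }
    stopifnot(abs(sum(rare$prob) - 1) < 1e-9)
    rare
  }
  stopifnot(n_patients >= 0, all(p_affected >= 0 & p_affected <= 1),
            all(p_other >= 0 & p_other <= 1),
            abs(sum(severity_probs) - 1) < 1e-2)
  severity_probs <- severity_probs / sum(severity_probs)
  structure(list(
    n_patients = as.integer(n_patients), p_affected = p_affected,
    arm_patterns = norm_pat("arm", arm_patterns),
    leg_patterns = norm_pat("leg", leg_patterns),
    p_other = p_other,
    arm_rare = norm_rare("arm", arm_rare),
    leg_rare = norm_rare("leg", leg_rare),
    severity_probs = severity_probs, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Default cohort specification from the published tables
#'
#' Common-pattern probabilities proportional to the published combination
#' counts (arms: 60/118, 20/118, ...; legs: 42/113, 24/113, ...), severity
#' probabilities (0.118, 0.412, 0.247, 0.223), side-independent laterality
#' calibrated to the bilateral fractions, and rare postures at their
#' observed rates.
#'
#' @inheritParams cohort_spec
#' @return a `cohort_spec`.
#' @export
default_cohort_spec <- function(n_patients = 85, seed = 1L) {
  cohort_spec(n_patients = n_patients, seed = seed)
}

#' Generate a synthetic cohort
#'
#' Each patient contributes two arms and two legs.  Every limb is affected
#' independently with the limb-type probability; an affected limb draws a
#' rare posture with probability `p_other`, otherwise a common combination
#' pattern.  Severity: a per-patient maximum grade is drawn from
#' `severity_probs`, assigned to one randomly chosen dystonic limb, and the
#' remaining dystonic limbs draw uniformly from the grades up to that
#' maximum (so the per-patient most-affected-extremity distribution matches
#' the specified mix).  The RNG state of the caller is preserved; the
#' cohort is a deterministic function of the spec.
#'
#' @param spec a [cohort_spec()].
#' @return a validated cohort data frame with attribute `seed`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  n <- spec$n_patients
  empty <- stats::setNames(
    as.data.frame(lapply(cohort_columns, function(x) character(0)),
                  stringsAsFactors = FALSE), cohort_columns)
  if (n == 0L) {
    attr(empty, "seed") <- spec$seed
    return(empty)
  }
  pid <- sprintf("synth-%05d", seq_len(n))

  # one block of n limbs (a given limb type and side), vectorized
  limb_block <- function(limb, side) {
    pats <- if (limb == "arm") spec$arm_patterns else spec$leg_patterns
    rare <- if (limb == "arm") spec$arm_rare else spec$leg_rare
    aff <- stats::runif(n) < spec$p_affected[[limb]]
    oth <- stats::runif(n) < spec$p_other[[limb]]
    pat_i <- sample.int(nrow(pats), n, replace = TRUE, prob = pats$prob)
    rare_i <- sample.int(nrow(rare), n, replace = TRUE, prob = rare$prob)
    block <- data.frame(patient_id = pid, side = side, limb = limb,
                        stringsAsFactors = FALSE)
    for (j in c(ARM_JOINTS, LEG_JOINTS))
      block[[j]] <- if (j %in% joints_for(limb)) "none" else NA_character_
    common <- aff & !oth
    ind <- COMMON_INDICATORS[[limb]]
    for (j in names(ind)) {
      lev <- strsplit(ind[[j]], "|", fixed = TRUE)[[1]][1]
      block[[j]][common & pats[[j]][pat_i]] <- lev
    }
    rare_rows <- which(aff & oth)
    for (k in rare_rows)
      block[[rare$joint[rare_i[k]]]][k] <- rare$posture[rare_i[k]]
    block$severity <- ifelse(aff, "slight", "none")  # graded below
    block
  }
  blocks <- list(limb_block("arm", "left"), limb_block("arm", "right"),
                 limb_block("leg", "left"), limb_block("leg", "right"))

  # per-patient severity: maximum grade drawn from the specified mix,
  # assigned to one random dystonic limb; other dystonic limbs draw
  # uniformly from the grades up to the maximum
  dyst <- sapply(blocks, function(b) b$severity != "none")
  gmax <- sample.int(4L, n, replace = TRUE, prob = spec$severity_probs)
  for (i in seq_len(n)) {
    idx <- which(dyst[i, ])
    if (!length(idx)) next
    worst <- idx[sample.int(length(idx), 1)]
    for (ii in idx) {
      g <- if (ii == worst) gmax[i] else sample.int(gmax[i], 1)
      blocks[[ii]]$severity[i] <- SEVERITY_LEVELS[g]
    }
  }
  cohort <- do.call(rbind, blocks)
  cohort <- cohort[order(rep(seq_len(n), 4L)), cohort_columns]
  rownames(cohort) <- NULL
  validate_cohort(cohort)
  attr(cohort, "seed") <- spec$seed
  cohort
}
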