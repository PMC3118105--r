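# Per-limb fixed-posture records and the cohort-level analyses: posture
# combination tables with marginal counts, the distal-to-proximal
# containment check, the exact left/right symmetry test and the per-patient
# severity summary.
#
# The unit of analysis is the limb (one row per limb), scored at four
# joints: arms at fingers/wrist/elbow/shoulder, legs at toes/ankle/knee/hip.
# A limb with "none" at every joint is a non-dystonic limb.

ARM_JOINTS <- c("fingers", "wrist", "elbow", "shoulder")
LEG_JOINTS <- c("toes", "ankle", "knee", "hip")
JOINT_LEVELS <- list(
  fingers = c("flexion", "extension", "none"),
  wrist = c("flexion", "extension", "none"),
  elbow = c("flexion", "pronation", "none"),
  shoulder = c("adduction", "none"),
  toes = c("plantar_flexion", "dorsiflexion", "none"),
  ankle = c("plantar_flexion", "inversion", "plantar_flexion_inversion",
            "dorsiflexion", "eversion", "dorsiflexion_inversion",
            "plantar_flexion_eversion", "none"),
  knee = c("flexion", "extension", "none"),
  hip = c("internal_rotation", "none"))
SEVERITY_LEVELS <- c("slight", "mild", "moderate", "severe")

# the four "common-pattern" indicators per limb type; ankle counts as
# involved in the common pattern for plantar flexion and/or inversion
COMMON_INDICATORS <- list(
  arm = c(fingers = "flexion", wrist = "flexion", elbow = "flexion",
          shoulder = "adduction"),
  leg = c(toes = "plantar_flexion",
          ankle = "plantar_flexion|inversion|plantar_flexion_inversion",
          knee = "flexion", hip = "internal_rotation"))

cohort_columns <- c("patient_id", "side", "limb", ARM_JOINTS, LEG_JOINTS,
                    "severity")

joints_for <- function(limb) if (limb == "arm") ARM_JOINTS else LEG_JOINTS

# TRUE where the joint value matches the limb's common-pattern indicator
indicator_matrix <- function(cohort, limb) {
  ind <- COMMON_INDICATORS[[limb]]
  sapply(names(ind), function(j) {
    cohort[[j]] %in% strsplit(ind[[j]], "|", fixed = TRUE)[[1]]
  })
}

is_dystonic <- function(cohort) {
  if (!nrow(cohort)) return(logical(0))
  involved <- function(j) !is.na(cohort[[j]]) & cohort[[j]] != "none"
  Reduce(`|`, lapply(c(ARM_JOINTS, LEG_JOINTS), involved))
}

#' Validate a cohort of per-limb posture records
#'
#' Checks the schema used throughout the package: one row per limb with
#' columns `patient_id`, `side` (left/right), `limb` (arm/leg), the four arm
#' joints (`fingers`, `wrist`, `elbow`, `shoulder`), the four leg joints
#' (`toes`, `ankle`, `knee`, `hip`) and `severity`.  Joints of the other
#' limb type must be `NA`; applicable joints must hold a known posture
#' category or `"none"`; `severity` is `"none"` exactly when all joints are
#' `"none"`; `(patient_id, side, limb)` must be unique.
#'
#' @param cohort a data frame.
#' @return the cohort, invisibly, with rows in input order.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  err <- function(bad, msg) {
    if (any(bad))
      stop("cohort row ", which(bad)[1], ": ", msg, call. = FALSE)
  }
  err(!cohort$side %in% c("left", "right"), "unknown side")
  err(!cohort$limb %in% c("arm", "leg"), "unknown limb (arm/leg)")
  is_arm <- cohort$limb == "arm"
  for (j in ARM_JOINTS) {
    err(is_arm & (is.na(cohort[[j]]) | !cohort[[j]] %in% JOINT_LEVELS[[j]]),
        paste0("unknown ", j, " category"))
    err(!is_arm & !is.na(cohort[[j]]),
        "arm joints must be NA on leg records")
  }
  for (j in LEG_JOINTS) {
    err(!is_arm & (is.na(cohort[[j]]) | !cohort[[j]] %in% JOINT_LEVELS[[j]]),
        paste0("unknown ", j, " category"))
    err(is_arm & !is.na(cohort[[j]]),
        "leg joints must be NA on arm records")
  }
  dyst <- is_dystonic(cohort)
  err(dyst & !cohort$severity %in% SEVERITY_LEVELS,
      "dystonic limb needs a severity grade (slight/mild/moderate/severe)")
  err(!dyst & cohort$severity != "none",
      "severity must be 'none' for a non-dystonic limb")
  key <- paste(cohort$patient_id, cohort$side, cohort$limb)
  if (anyDuplicated(key))
    stop("duplicate (patient_id, side, limb): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  invisible(cohort)
}

#' Read a cohort file
#'
#' Reads a comma-separated cohort file (UTF-8, header row, empty fields =
#' `NA`) and validates it with [validate_cohort()].  Lines starting with
#' `#` are treated as comments.
#'
#' @param path file path.
#' @return a validated cohort data frame.
#' @export
load_cohort <- function(path) {
  cohort <- utils::read.csv(path, colClasses = "character",
                            na.strings = "", comment.char = "#",
                            stringsAsFactors = FALSE)
  validate_cohort(cohort)
  cohort
}

#' Write a cohort file
#'
#' Inverse of [load_cohort()]: comma-separated, UTF-8, header row, `NA`
#' written as an empty field.  Round-trips exactly.
#'
#' @param cohort a cohort data frame.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort[cohort_columns], path, row.names = FALSE,
                   na = "", quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Posture combination table
#'
#' Maps every dystonic limb of the requested type to its four-bit
#' common-pattern indicator (arms: finger flexion, wrist flexion, elbow
#' flexion, shoulder adduction; legs: toe plantar flexion, ankle plantar
#' flexion and/or inversion, knee flexion, hip internal rotation) and
#' tabulates the distinct combinations by count.  Dystonic limbs whose four
#' indicators are all absent (rare postures only) are excluded from the
#' table and counted as "other-pattern" limbs.
#'
#' @param cohort a validated cohort data frame.
#' @param limb `"arm"` or `"leg"`.
#' @return an object of class `combination_table`: a data frame with one
#'   logical column per indicator joint plus `count`, ordered by decreasing
#'   count, with attributes `limb`, `column_totals`, `grand_total`,
#'   `other_pattern` (dystonic limbs with no indicator) and `non_dystonic`.
#' @export
combination_table <- function(cohort, limb = c("arm", "leg")) {
  limb <- match.arg(limb)
  sub <- cohort[cohort$limb == limb, , drop = FALSE]
  joints <- joints_for(limb)
  empty <- function() {
    tab <- as.data.frame(matrix(logical(0), 0, 4,
                                dimnames = list(NULL, joints)))
    tab$count <- integer(0)
    structure(tab, class = c("combination_table", "data.frame"), limb = limb,
              column_totals = stats::setNames(integer(4), joints),
              grand_total = 0L, other_pattern = 0L, non_dystonic = 0L)
  }
  if (!nrow(sub)) return(empty())
  dyst <- is_dystonic(sub)
  ind <- indicator_matrix(sub, limb)
  if (is.null(dim(ind))) ind <- matrix(ind, nrow = nrow(sub))
  colnames(ind) <- joints
  has_common <- rowSums(ind) > 0
  keep <- dyst & has_common
  other_pattern <- sum(dyst & !has_common)
  if (!any(keep)) {
    out <- empty()
    attr(out, "other_pattern") <- other_pattern
    attr(out, "non_dystonic") <- sum(!dyst)
    return(out)
  }
  key <- apply(ind[keep, , drop = FALSE], 1,
               function(r) paste(as.integer(r), collapse = ""))
  counts <- sort(table(key), decreasing = TRUE)
  tab <- as.data.frame(t(sapply(names(counts), function(k)
    as.logical(as.integer(strsplit(k, "")[[1]])))))
  names(tab) <- joints
  rownames(tab) <- NULL
  tab$count <- as.integer(counts)
  structure(tab, class = c("combination_table", "data.frame"), limb = limb,
            column_totals = stats::setNames(
              as.integer(colSums(ind[keep, , drop = FALSE])), joints),
            grand_total = sum(keep), other_pattern = other_pattern,
            non_dystonic = sum(!dyst))
}

#' Marginal counts of a combination table
#'
#' @param table a [combination_table()].
#' @return a list with `total` (limbs with at least one common-pattern
#'   indicator) and `joints` (named vector of per-joint indicator totals).
#' @export
marginal_counts <- function(table) {
  stopifnot(inherits(table, "combination_table"))
  list(total = attr(table, "grand_total"),
       joints = attr(table, "column_totals"))
}

#' @export
print.combination_table <- function(x, ...) {
  cat("<combination_table> ", attr(x, "limb"), "s: ", attr(x, "grand_total"),
      " limbs in ", nrow(x), " patterns (+", attr(x, "other_pattern"),
      " other-pattern, +", attr(x, "non_dystonic"), " non-dystonic)\n", sep = "")
  print(as.data.frame(x), ...)
  cat("column totals:",
      paste(names(attr(x, "column_totals")), attr(x, "column_totals"),
            sep = "="), "\n")
  invisible(x)
}

#' Distal-to-proximal containment check
#'
#' In the study cohort, proximal joint involvement was always accompanied by
#' involvement of the distal end of the limb: every arm with shoulder
#' adduction also had affected fingers, and every leg with hip involvement
#' an affected ankle.  Returns the records violating that property (empty =
#' property holds).
#'
#' @inheritParams combination_table
#' @return the violating rows of `cohort`.
#' @export
proximal_distal_containment <- function(cohort, limb = c("arm", "leg")) {
  limb <- match.arg(limb)
  sub <- cohort[cohort$limb == limb, , drop = FALSE]
  if (!nrow(sub)) return(sub)
  if (limb == "arm") {
    bad <- sub$shoulder != "none" & sub$fingers == "none"
  } else {
    bad <- sub$hip != "none" & sub$ankle == "none"
  }
  sub[bad, , drop = FALSE]
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables with the observed margins whose
# probability does not exceed the observed table's (with a 1e-7 relative
# slack against floating-point ties).
fisher_p_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2), all(tab >= 0))
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (m == 0 || n == 0 || k == 0 || sum(tab[, 2]) == 0) {
    warning("degenerate 2x2 table (zero margin); p = 1")
    return(1)
  }
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
}

#' Exact test of left/right symmetry
#'
#' Builds the 2x2 table side x dystonia-present over the limbs of the given
#' type and computes the two-sided Fisher exact p-value by full
#' hypergeometric enumeration (summing the probabilities of all tables with
#' the observed margins that are no more probable than the observed one).
#' A degenerate table (zero margin) yields p = 1 with a warning.
#'
#' @inheritParams combination_table
#' @return a list with `p.value`, the 2x2 `table` (rows = side, columns =
#'   dystonic yes/no) and `method`.
#' @export
lr_symmetry_test <- function(cohort, limb = c("arm", "leg")) {
  limb <- match.arg(limb)
  sub <- cohort[cohort$limb == limb, , drop = FALSE]
  if (!nrow(sub)) stop("no ", limb, " records in cohort")
  dyst <- is_dystonic(sub)
  tab <- matrix(c(sum(sub$side == "left" & dyst),
                  sum(sub$side == "left" & !dyst),
                  sum(sub$side == "right" & dyst),
                  sum(sub$side == "right" & !dyst)),
                nrow = 2, byrow = TRUE,
                dimnames = list(side = c("left", "right"),
                                dystonic = c("yes", "no")))
  list(p.value = fisher_p_2x2(tab), table = tab,
       method = "two-sided Fisher exact test (hypergeometric enumeration)")
}

#' Per-patient severity of the most affected extremity
#'
#' The severity assigned to a patient is the maximum Burke-Fahn-Marsden
#' severity grade (slight < mild < moderate < severe) over the patient's
#' dystonic limbs.  Patients without any dystonic limb are excluded.
#'
#' @param cohort a validated cohort data frame.
#' @return a data frame with `severity`, `n` and `percent` per grade.
#' @export
severity_summary <- function(cohort) {
  dyst <- is_dystonic(cohort)
  sub <- cohort[dyst, , drop = FALSE]
  if (!nrow(sub))
    return(data.frame(severity = SEVERITY_LEVELS, n = 0L, percent = NaN))
  sev <- as.integer(factor(sub$severity, levels = SEVERITY_LEVELS))
  worst <- tapply(sev, sub$patient_id, max)
  counts <- table(factor(SEVERITY_LEVELS[worst], levels = SEVERITY_LEVELS))
  data.frame(severity = SEVERITY_LEVELS, n = as.integer(counts),
             percent = 100 * as.integer(counts) / sum(counts))
}
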