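# Quantitative operationalization of the five clinical characteristics of
# CRPS-related fixed dystonia, scored on a simulated condition relative to
# the reference run:
#   (i)   abnormal posture
#   (ii)  sustained contraction
#   (iii) increased stiffness
#   (iv)  worsening with activity
#   (v)   loss of voluntary control
# No published numeric criteria exist for these characteristics; the
# thresholds below are one documented operationalization, calibrated so the
# reference run scores 0 and the qualitative regime map of the aberrant
# conditions holds, and reported alongside every score.

#' Score thresholds
#'
#' @param theta_posture posture threshold \[rad\]: final resting angle beyond
#'   which a posture counts as abnormal.
#' @param act_rest minimum excess resting activation (over the reference) of
#'   the *less* active muscle for contraction to count as sustained — keying
#'   on the minimum of the pair makes this a co-contraction detector.
#' @param stiffness_ratio fraction of the reference's force-phase deflection
#'   below which the joint counts as stiffened (in (0, 1)).
#' @param worsen_margin minimum increase \[rad\] of the resting deviation from
#'   the first to the final rest phase.
#' @param voluntary_ratio fraction of the reference's voluntary-phase
#'   excursion below which voluntary control counts as lost (in (0, 1)).
#' @return a list of class `score_thresholds`.
#' @export
score_thresholds <- function(theta_posture = 0.05, act_rest = 0.05,
                             stiffness_ratio = 0.5, worsen_margin = 0.02,
                             voluntary_ratio = 0.5) {
  th <- list(theta_posture = theta_posture, act_rest = act_rest,
             stiffness_ratio = stiffness_ratio, worsen_margin = worsen_margin,
             voluntary_ratio = voluntary_ratio)
  if (any(unlist(th) <= 0)) stop("all thresholds must be > 0")
  if (stiffness_ratio >= 1 || voluntary_ratio >= 1)
    stop("ratio thresholds must be < 1")
  structure(th, class = "score_thresholds")
}

# mean of a series over the time window [t0, t1]
window_mean <- function(t, x, t0, t1) mean(x[t >= t0 & t <= t1])

#' Score a simulated condition against the five dystonia characteristics
#'
#' All criteria are relative to the reference run, which must share the
#' protocol and time grid.  With phase boundaries at `5, 10, 15, 20` s
#' (durations scale with the protocol):
#' * *abnormal posture*: |mean angle over the last second| exceeds
#'   `theta_posture`;
#' * *sustained contraction*: the less active muscle's mean activation over
#'   the final rest exceeds the reference's by more than `act_rest`
#'   (co-contraction);
#' * *increased stiffness*: the deflection induced by the external torque
#'   (|mean angle over the settled part of the force phase, relative to the
#'   run's own final resting posture|) is below `stiffness_ratio` times the
#'   reference's deflection;
#' * *worsening with activity*: an abnormal resting posture is present and
#'   the deviation during the voluntary phase exceeds the run's own resting
#'   posture by more than `worsen_margin` — activity deepens the dystonic
#'   posture.  (Anchoring on the abnormal posture keeps the reference, whose
#'   voluntary movement is a normal excursion from neutral, at FALSE; see
#'   the methods vignette for why a rest-to-rest comparison is degenerate in
#'   this model class.)
#' * *loss of voluntary control*: the voluntary-phase excursion (mean angle
#'   over its settled part minus the preceding resting posture) is below
#'   `voluntary_ratio` times the reference's excursion.
#'
#' @param result,reference `dystonia_sim` objects on the same grid.
#' @param th a [score_thresholds()] object.
#' @return a list of class `dystonia_score` with the five logical flags,
#'   `total` (0-5) and the thresholds used.
#' @export
score_dystonia <- function(result, reference, th = score_thresholds()) {
  stopifnot(inherits(result, "dystonia_sim"), inherits(reference, "dystonia_sim"))
  if (nrow(result$data) != nrow(reference$data) ||
      !isTRUE(all.equal(result$data$t - result$data$t[1],
                        reference$data$t - reference$data$t[1])))
    stop("result and reference must share the protocol time grid")
  d <- result$data; rd <- reference$data
  tt <- d$t - d$t[1]  # scores are invariant to a common time offset
  dur <- attr(result$meta$protocol, "duration")
  ph <- dur / 4  # phase length

  rest1 <- c(2 * ph - 1, 2 * ph)   # last 1 s of first rest
  restF <- c(4 * ph - 1, 4 * ph)   # last 1 s of final rest
  forceW <- c(0.6 * ph, ph)        # settled part of the force phase
  volW <- c(2 * ph + 0.6 * ph, 3 * ph)  # settled part of voluntary phase

  posture <- window_mean(tt, d$theta, restF[1], restF[2])
  posture1 <- window_mean(tt, d$theta, rest1[1], rest1[2])
  posture_ref <- window_mean(tt, rd$theta, restF[1], restF[2])

  co_act <- min(window_mean(tt, d$a_flex, restF[1], restF[2]),
                window_mean(tt, d$a_ext, restF[1], restF[2]))
  co_act_ref <- min(window_mean(tt, rd$a_flex, restF[1], restF[2]),
                    window_mean(tt, rd$a_ext, restF[1], restF[2]))

  defl <- abs(window_mean(tt, d$theta, forceW[1], forceW[2]) - posture)
  defl_ref <- abs(window_mean(tt, rd$theta, forceW[1], forceW[2]) - posture_ref)

  vol <- abs(window_mean(tt, d$theta, volW[1], volW[2]) - posture1)
  vol_ref <- abs(window_mean(tt, rd$theta, volW[1], volW[2]) -
                 window_mean(tt, rd$theta, rest1[1], rest1[2]))

  vol_mean <- window_mean(tt, d$theta, volW[1], volW[2])
  abnormal <- abs(posture) > th$theta_posture
  flags <- c(
    abnormal_posture = abnormal,
    sustained_contraction = co_act - co_act_ref > th$act_rest,
    increased_stiffness = defl < th$stiffness_ratio * defl_ref,
    worsening_with_activity = abnormal &&
      abs(vol_mean) - abs(posture) > th$worsen_margin,
    loss_of_voluntary_control = vol < th$voluntary_ratio * vol_ref)
  flags[is.na(flags)] <- FALSE  # unstable runs: undefined criteria not met

  structure(c(as.list(flags), list(total = sum(flags), thresholds = th,
                                   label = result$meta$label)),
            class = "dystonia_score")
}

#' Score a whole battery
#'
#' @param battery named list of `dystonia_sim` objects as produced by
#'   [run_battery()]; must contain a `reference` element.
#' @param th a [score_thresholds()] object.
#' @return a data frame with one row per condition: label, the five logical
#'   flags and `total`.
#' @export
score_battery <- function(battery, th = score_thresholds()) {
  stopifnot("reference" %in% names(battery))
  rows <- lapply(names(battery), function(lbl) {
    s <- score_dystonia(battery[[lbl]], battery$reference, th)
    data.frame(condition = lbl,
               abnormal_posture = s$abnormal_posture,
               sustained_contraction = s$sustained_contraction,
               increased_stiffness = s$increased_stiffness,
               worsening_with_activity = s$worsening_with_activity,
               loss_of_voluntary_control = s$loss_of_voluntary_control,
               total = s$total)
  })
  do.call(rbind, rows)
}

#' @export
print.dystonia_score <- function(x, ...) {
  cat("<dystonia_score> ", x$label, ": total ", x$total, "/5\n", sep = "")
  flags <- c("abnormal_posture", "sustained_contraction", "increased_stiffness",
             "worsening_with_activity", "loss_of_voluntary_control")
  for (f in flags) cat("  ", format(f, width = 26), if (x[[f]]) "yes" else "no", "\n")
  invisible(x)
}
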