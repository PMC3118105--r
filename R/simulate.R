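# Delay-aware fixed-step integration of the coupled joint-muscle-reflex
# system, the 20 s input protocol and the 1 + 9 condition battery.
#
# Integrator: explicit fixed-step RK4 on the six continuous states
# (theta, omega, a_flex, l_ce_flex, a_ext, l_ce_ext).  Delayed reflex
# signals are read from a recorded signal history at exact multiples of the
# step (delays are validated to be grid multiples); the neural drive is
# evaluated per RK4 stage, with the midpoint stages using the mean of the
# step-start and step-end delayed values.  History before t = 0 is pinned
# at the neutral-rest equilibrium of the *reference* configuration, so
# every aberrant condition starts from the same resting state.

#' The four-phase input protocol
#'
#' Every simulated condition uses the same 20 s protocol: five seconds of
#' continuous external torque, five seconds of rest, five seconds of
#' continuous voluntary contraction (a constant excitation added to the
#' agonist's drive), and a final five seconds of rest.
#'
#' @param t_force external torque amplitude \[N m\] applied during the first
#'   phase; positive = flexion-assisting.
#' @param u_vol voluntary excitation level in \[0, 1\] applied to the agonist
#'   (flexor) during the third phase.
#' @param phase_dur duration of each phase \[s\].
#' @return a data frame of class `input_protocol` with columns `t_start`,
#'   `t_end`, `t_external`, `u_voluntary`, and attribute `duration`.
#' @export
build_protocol <- function(t_force, u_vol, phase_dur = 5) {
  stopifnot(is.finite(t_force), u_vol >= 0, u_vol <= 1, phase_dur > 0)
  p <- data.frame(
    t_start = phase_dur * 0:3,
    t_end = phase_dur * 1:4,
    t_external = c(t_force, 0, 0, 0),
    u_voluntary = c(0, 0, u_vol, 0))
  structure(p, class = c("input_protocol", "data.frame"),
            duration = 4 * phase_dur)
}

#' Integrator settings
#'
#' @param dt step size \[s\]; must be positive and smaller than a quarter of
#'   the shortest reflex delay (checked at simulation time).
#' @param theta_bound hard physical bound on the joint angle \[rad\]; a
#'   trajectory exceeding it (or turning non-finite) is flagged unstable.
#' @return a list of class `simulation_settings`.
#' @export
simulation_settings <- function(dt = 2.5e-4, theta_bound = 3) {
  stopifnot(dt > 0, theta_bound > 0)
  structure(list(dt = dt, theta_bound = theta_bound),
            class = "simulation_settings")
}

# Neutral-rest equilibrium of one muscle under a given tonic drive law.
# At neutral the spindle signals are zero by construction, so the resting
# drive is the offsets plus force feedback: u = clip(e_sum + k_f * F/f_max).
# Solves F_se(l0 - l_ce) = max(u, A_MIN) * f_max * fl(l_ce) for l_ce.
rest_equilibrium <- function(mp, entry) {
  l0 <- mp$l_ce_opt + mp$l_se_slack
  e_sum <- entry$e_p + entry$e_v + entry$e_f
  g <- function(l_ce) {
    f <- se_force(l0 - l_ce, mp)
    u <- min(max(e_sum + entry$k_f * f / mp$f_max, 0), 1)
    f - max(u, A_MIN) * mp$f_max * force_length(l_ce, mp)
  }
  sol <- stats::uniroot(g, c(0.5 * mp$l_ce_opt, mp$l_ce_opt), tol = 1e-12)
  l_ce <- sol$root
  f <- se_force(l0 - l_ce, mp)
  u <- min(max(e_sum + entry$k_f * f / mp$f_max, 0), 1)
  list(l_ce = l_ce, a = max(u, A_MIN), force = f)
}

#' Simulate one condition
#'
#' Integrates the antagonistic pair with reflex feedback under the given
#' protocol.  Deterministic: no randomness is involved and identical inputs
#' reproduce identical output.
#'
#' @param preset a `dystonia_preset` from [load_preset()].
#' @param reflex_cfg the [reflex_config()] to simulate (typically
#'   [apply_scenario()] applied to `preset$reflex`).
#' @param protocol an [build_protocol()] object; defaults to the preset's
#'   amplitudes.
#' @param settings a [simulation_settings()] object.
#' @param label condition label stored in the metadata.
#' @return an object of class `dystonia_sim`: a list with `data` (data frame
#'   with columns `t`, `theta`, `omega`, `a_flex`, `a_ext`, `f_flex`,
#'   `f_ext`, `torque_flex`, `torque_ext`, `u_reflex_flex`, `u_reflex_ext`)
#'   and `meta` (preset name, label, settings, `unstable` flag,
#'   `deterministic = TRUE`).
#' @export
simulate_condition <- function(preset, reflex_cfg = preset$reflex,
                               protocol = NULL,
                               settings = simulation_settings(),
                               label = "condition") {
  stopifnot(inherits(preset, "dystonia_preset"),
            inherits(reflex_cfg, "reflex_config"))
  if (is.null(protocol))
    protocol <- build_protocol(preset$protocol$t_force,
                               preset$protocol$u_voluntary)
  dt <- settings$dt
  mf <- preset$flexor; me <- preset$extensor; jp <- preset$joint
  rf <- reflex_cfg$flexor; re <- reflex_cfg$extensor
  delays <- c(rf$tau_p, rf$tau_v, rf$tau_f, re$tau_p, re$tau_v, re$tau_f)
  if (dt >= min(delays) / 4)
    stop("`dt` must be smaller than a quarter of the shortest reflex delay")
  dsteps <- delays / dt
  if (any(abs(dsteps - round(dsteps)) > 1e-9))
    stop("reflex delays must be integer multiples of `dt`")
  dsteps <- as.integer(round(dsteps))

  duration <- attr(protocol, "duration")
  n <- as.integer(round(duration / dt))
  tgrid <- dt * (0:n)

  # piecewise-constant inputs on [t_k, t_{k+1})
  text_k <- numeric(n + 1L); uvol_k <- numeric(n + 1L)
  for (i in seq_len(nrow(protocol))) {
    sel <- tgrid >= protocol$t_start[i] & tgrid < protocol$t_end[i]
    text_k[sel] <- protocol$t_external[i]
    uvol_k[sel] <- protocol$u_voluntary[i]
  }
  text_k[n + 1L] <- protocol$t_external[nrow(protocol)]
  uvol_k[n + 1L] <- protocol$u_voluntary[nrow(protocol)]

  # reference rest equilibrium: initial state, spindle neutral length and
  # pre-t=0 signal history for both muscles
  eq_f <- rest_equilibrium(mf, preset$reflex$flexor)
  eq_e <- rest_equilibrium(me, preset$reflex$extensor)
  lce_f0 <- eq_f$l_ce; lce_e0 <- eq_e$l_ce

  # unpack scalars for the inner loop
  fmax_f <- mf$f_max; lopt_f <- mf$l_ce_opt; lsl_f <- mf$l_se_slack
  ksh_f <- mf$k_se_shape; wfl_f <- mf$w_fl
  vm_f <- mf$v_max * lopt_f; ah_f <- mf$a_hill
  ta_f <- mf$tau_act; td_f <- mf$tau_deact; r_f <- mf$r
  fmax_e <- me$f_max; lopt_e <- me$l_ce_opt; lsl_e <- me$l_se_slack
  ksh_e <- me$k_se_shape; wfl_e <- me$w_fl
  vm_e <- me$v_max * lopt_e; ah_e <- me$a_hill
  ta_e <- me$tau_act; td_e <- me$tau_deact; r_e <- me$r
  l0_f <- lopt_f + lsl_f; l0_e <- lopt_e + lsl_e
  inertia <- jp$inertia; b_pass <- jp$b_passive
  becc_f <- (FV_ECC - 1) * vm_f * ah_f / (1 + ah_f)
  becc_e <- (FV_ECC - 1) * vm_e * ah_e / (1 + ah_e)
  sedenom_f <- exp(ksh_f) - 1; sedenom_e <- exp(ksh_e) - 1
  phi_cap <- FV_ECC - 0.01
  kp_f <- rf$k_p; kv_f <- rf$k_v; kf_f <- rf$k_f
  off_f <- rf$e_p + rf$e_v + rf$e_f
  kp_e <- re$k_p; kv_e <- re$k_v; kf_e <- re$k_f
  off_e <- re$e_p + re$e_v + re$e_f
  d1 <- dsteps[1]; d2 <- dsteps[2]; d3 <- dsteps[3]
  d4 <- dsteps[4]; d5 <- dsteps[5]; d6 <- dsteps[6]

  # state: theta, omega, a_f, lce_f, a_e, lce_e.  Per-muscle mechanics are
  # inlined (scalar form of muscle_force()/fv_inverse(), kept in step by a
  # consistency property test) for inner-loop speed.
  deriv <- function(y, uf, ue, text) {
    # flexor
    eps <- (l0_f - r_f * y[1] - y[4] - lsl_f) / lsl_f
    ff <- if (eps > 0) fmax_f * (exp(ksh_f * eps / SE_STRAIN_REF) - 1) / sedenom_f else 0
    fl <- exp(-((y[4] / lopt_f - 1) / wfl_f)^2)
    if (fl < FL_MIN) fl <- FL_MIN
    phi <- ff / (max(y[3], A_MIN) * fmax_f * fl)
    if (phi > phi_cap) phi <- phi_cap
    vf <- if (phi <= 1) vm_f * (phi - 1) / (1 + phi / ah_f)
          else becc_f * ((FV_ECC - 1) / (FV_ECC - phi) - 1)
    # extensor
    eps <- (l0_e + r_e * y[1] - y[6] - lsl_e) / lsl_e
    fe <- if (eps > 0) fmax_e * (exp(ksh_e * eps / SE_STRAIN_REF) - 1) / sedenom_e else 0
    fl <- exp(-((y[6] / lopt_e - 1) / wfl_e)^2)
    if (fl < FL_MIN) fl <- FL_MIN
    phi <- fe / (max(y[5], A_MIN) * fmax_e * fl)
    if (phi > phi_cap) phi <- phi_cap
    ve <- if (phi <= 1) vm_e * (phi - 1) / (1 + phi / ah_e)
          else becc_e * ((FV_ECC - 1) / (FV_ECC - phi) - 1)
    c(y[2],
      (r_f * ff - r_e * fe - b_pass * y[2] + text) / inertia,
      (uf - y[3]) / (if (uf > y[3]) ta_f else td_f),
      vf,
      (ue - y[5]) / (if (ue > y[5]) ta_e else td_e),
      ve)
  }

  # output and signal-history arrays
  theta <- omega <- a_f <- a_e <- f_f <- f_e <- numeric(n + 1L)
  urx_f <- urx_e <- numeric(n + 1L)
  sp_f <- sv_f <- sf_f <- numeric(n + 1L)
  sp_e <- sv_e <- sf_e <- numeric(n + 1L)

  y <- c(0, 0, eq_f$a, lce_f0, eq_e$a, lce_e0)
  rest_sf_f <- eq_f$force / fmax_f; rest_sf_e <- eq_e$force / fmax_e
  unstable <- FALSE
  kstop <- n + 1L

  for (k in 1:(n + 1L)) {
    theta[k] <- y[1]; omega[k] <- y[2]
    a_f[k] <- y[3]; a_e[k] <- y[5]
    # instantaneous forces and CE velocities at the step start (same
    # mechanics as deriv())
    eps <- (l0_f - r_f * y[1] - y[4] - lsl_f) / lsl_f
    ff <- if (eps > 0) fmax_f * (exp(ksh_f * eps / SE_STRAIN_REF) - 1) / sedenom_f else 0
    fl <- exp(-((y[4] / lopt_f - 1) / wfl_f)^2)
    if (fl < FL_MIN) fl <- FL_MIN
    phi <- ff / (max(y[3], A_MIN) * fmax_f * fl)
    if (phi > phi_cap) phi <- phi_cap
    vf <- if (phi <= 1) vm_f * (phi - 1) / (1 + phi / ah_f)
          else becc_f * ((FV_ECC - 1) / (FV_ECC - phi) - 1)
    eps <- (l0_e + r_e * y[1] - y[6] - lsl_e) / lsl_e
    fe <- if (eps > 0) fmax_e * (exp(ksh_e * eps / SE_STRAIN_REF) - 1) / sedenom_e else 0
    fl <- exp(-((y[6] / lopt_e - 1) / wfl_e)^2)
    if (fl < FL_MIN) fl <- FL_MIN
    phi <- fe / (max(y[5], A_MIN) * fmax_e * fl)
    if (phi > phi_cap) phi <- phi_cap
    ve <- if (phi <= 1) vm_e * (phi - 1) / (1 + phi / ah_e)
          else becc_e * ((FV_ECC - 1) / (FV_ECC - phi) - 1)
    f_f[k] <- ff; f_e[k] <- fe
    sp_f[k] <- max((y[4] - lce_f0) / lopt_f, 0)
    sp_e[k] <- max((y[6] - lce_e0) / lopt_e, 0)
    sv_f[k] <- max(vf / lopt_f, 0); sv_e[k] <- max(ve / lopt_e, 0)
    sf_f[k] <- ff / fmax_f; sf_e[k] <- fe / fmax_e

    # delayed reflex drive (history before t = 0 is the reference rest):
    # each pathway is read at its own latency, at the step start (stage 1)
    # and the step end (stage 4); the RK4 midpoint uses the average
    i1 <- k - d1; i2 <- k - d2; i3 <- k - d3
    i4 <- k - d4; i5 <- k - d5; i6 <- k - d6
    urx_f[k] <- kp_f * (if (i1 >= 1L) sp_f[i1] else 0) +
      kv_f * (if (i2 >= 1L) sv_f[i2] else 0) +
      kf_f * (if (i3 >= 1L) sf_f[i3] else rest_sf_f) + off_f
    urx_e[k] <- kp_e * (if (i4 >= 1L) sp_e[i4] else 0) +
      kv_e * (if (i5 >= 1L) sv_e[i5] else 0) +
      kf_e * (if (i6 >= 1L) sf_e[i6] else rest_sf_e) + off_e
    if (k > n) break

    drv_f4 <- kp_f * (if (i1 >= 0L) sp_f[i1 + 1L] else 0) +
      kv_f * (if (i2 >= 0L) sv_f[i2 + 1L] else 0) +
      kf_f * (if (i3 >= 0L) sf_f[i3 + 1L] else rest_sf_f) + off_f
    drv_e4 <- kp_e * (if (i4 >= 0L) sp_e[i4 + 1L] else 0) +
      kv_e * (if (i5 >= 0L) sv_e[i5 + 1L] else 0) +
      kf_e * (if (i6 >= 0L) sf_e[i6 + 1L] else rest_sf_e) + off_e

    uvol <- uvol_k[k]
    uf1 <- min(max(uvol + urx_f[k], 0), 1)
    ue1 <- min(max(urx_e[k], 0), 1)
    uf4 <- min(max(uvol + drv_f4, 0), 1)
    ue4 <- min(max(drv_e4, 0), 1)
    uf2 <- (uf1 + uf4) / 2
    ue2 <- (ue1 + ue4) / 2
    text <- text_k[k]

    k1 <- deriv(y, uf1, ue1, text)
    k2 <- deriv(y + dt / 2 * k1, uf2, ue2, text)
    k3 <- deriv(y + dt / 2 * k2, uf2, ue2, text)
    k4 <- deriv(y + dt * k3, uf4, ue4, text)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    # activation saturates at its fixed point; guard rounding excursions
    y[3] <- min(max(y[3], 0), 1); y[5] <- min(max(y[5], 0), 1)

    if (!all(is.finite(y)) || abs(y[1]) > settings$theta_bound) {
      unstable <- TRUE
      kstop <- k
      break
    }
  }
  if (unstable && kstop < n + 1L) {
    idx <- (kstop + 1L):(n + 1L)
    theta[idx] <- omega[idx] <- a_f[idx] <- a_e[idx] <- NA_real_
    f_f[idx] <- f_e[idx] <- urx_f[idx] <- urx_e[idx] <- NA_real_
  }

  structure(list(
    data = data.frame(
      t = tgrid, theta = theta, omega = omega,
      a_flex = a_f, a_ext = a_e, f_flex = f_f, f_ext = f_e,
      torque_flex = r_f * f_f, torque_ext = -r_e * f_e,
      u_reflex_flex = urx_f, u_reflex_ext = urx_e),
    meta = list(preset = preset$name, label = label, dt = dt,
                protocol = protocol, settings = settings,
                unstable = unstable, deterministic = TRUE)),
    class = "dystonia_sim")
}

#' Run the reference + nine aberrant conditions
#'
#' Applies each of the three aberrant scenarios to each of the three reflex
#' pathways (nine conditions) plus the unmodified reference, all under the
#' identical protocol, and returns the ten results.
#'
#' @inheritParams simulate_condition
#' @param magnitude_sens gain multiplier for the two sensitivity scenarios.
#' @param magnitude_offset offset level for the offset scenario.
#' @param agonist muscle carrying the imbalanced aberrations.
#' @return named list of `dystonia_sim` objects: `reference`,
#'   `<scenario>_<pathway>` for the nine aberrant conditions.
#' @export
run_battery <- function(preset, magnitude_sens = 4, magnitude_offset = 0.025,
                        protocol = NULL, settings = simulation_settings(),
                        agonist = "flexor") {
  specs <- list(scenario_spec("reference"))
  for (sc in setdiff(SCENARIOS, "reference"))
    for (pw in PATHWAYS) {
      mag <- if (sc == "imbalanced_offset") magnitude_offset else magnitude_sens
      specs <- c(specs, list(scenario_spec(sc, pw, mag, agonist)))
    }
  out <- lapply(specs, function(sp) {
    simulate_condition(preset, apply_scenario(preset$reflex, sp),
                       protocol = protocol, settings = settings,
                       label = condition_label(sp))
  })
  names(out) <- vapply(specs, condition_label, character(1))
  out
}

#' @export
print.dystonia_sim <- function(x, ...) {
  cat("<dystonia_sim> ", x$meta$preset, " / ", x$meta$label,
      if (isTRUE(x$meta$unstable)) "  [UNSTABLE]" else "", "\n", sep = "")
  cat("  ", nrow(x$data), " samples, dt = ", x$meta$dt, " s, final theta = ",
      format(x$data$theta[nrow(x$data)], digits = 4), " rad\n", sep = "")
  invisible(x)
}

#' Count oscillation zero-crossings
#'
#' Counts sign changes of the angular velocity, keeping only crossings whose
#' preceding velocity peak exceeds `omega_min` (so numerical jitter around a
#' settled posture is not counted), and returns the maximum number of such
#' crossings falling inside any sliding window of `window` seconds.  Five or
#' more crossings within two seconds is the criterion used for "fast
#' oscillatory movements".
#'
#' @param result a `dystonia_sim` object.
#' @param omega_min minimum |angular velocity| peak \[rad/s\] between counted
#'   crossings.
#' @param window window length \[s\].
#' @return integer crossing count (`Inf` if the run went unstable).
#' @export
oscillation_count <- function(result, omega_min = 0.05, window = 2) {
  om <- result$data$omega
  if (anyNA(om)) return(Inf)
  tt <- result$data$t
  cross <- numeric(0)
  lastpeak <- 0
  for (k in 2:length(om)) {
    ak <- abs(om[k])
    if (ak > lastpeak) lastpeak <- ak
    if (om[k - 1] * om[k] < 0 && lastpeak >= omega_min) {
      cross <- c(cross, tt[k])
      lastpeak <- 0
    }
  }
  if (!length(cross)) return(0L)
  mx <- 0L
  for (tc in cross) mx <- max(mx, sum(cross >= tc & cross < tc + window))
  mx
}
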