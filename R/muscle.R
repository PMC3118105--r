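# Hill-type musculotendon mechanics for one muscle of an antagonistic pair,
# and the single-degree-of-freedom joint (hand or arm segment) they act on.
#
# Model structure: a contractile element (CE) with activation-scaled
# force-length and force-velocity behaviour in series with an exponential
# series-elastic element (SE).  No parallel-elastic element: passive joint
# behaviour comes from the SE, a small tonic drive floor and viscous joint
# damping.  CE velocity is obtained by inverting the force-velocity relation
# at the current SE force (DAE reduction), so each muscle carries exactly two
# continuous states: activation `a` and CE length `l_ce`.

# Eccentric force plateau (multiple of isometric force) and SE strain at
# maximal isometric force.  Activation floor used when inverting the
# force-velocity relation; represents a minimal tonic drive and keeps the
# inversion defined as a -> 0.
FV_ECC <- 1.3
SE_STRAIN_REF <- 0.04
A_MIN <- 0.005
FL_MIN <- 1e-3

#' Musculotendon parameter set
#'
#' Bundles the constants of one Hill-type muscle: maximal isometric force,
#' optimal contractile-element (CE) length, series-elastic (SE) slack length
#' and exponential shape, force-length width, maximal shortening velocity,
#' force-velocity curvature, activation/deactivation time constants, a
#' constant moment arm and a sign flag giving the muscle's pulling direction
#' on the joint (+1 flexor, -1 extensor; flexion is the positive joint
#' direction).
#'
#' @param f_max maximal isometric force \[N\].
#' @param l_ce_opt optimal CE length \[m\].
#' @param l_se_slack SE slack length \[m\].
#' @param k_se_shape dimensionless exponential shape of the SE force-strain
#'   curve (larger = stiffer toe region).
#' @param w_fl dimensionless force-length width: the active force-length
#'   factor is `exp(-((l_ce/l_ce_opt - 1)/w_fl)^2)`.
#' @param v_max maximal shortening velocity \[optimal CE lengths per s\].
#' @param a_hill dimensionless Hill force-velocity curvature.
#' @param tau_act,tau_deact activation and deactivation time constants \[s\];
#'   `tau_act <= tau_deact`.
#' @param r constant moment arm about the joint \[m\].
#' @param sign +1 for the flexor, -1 for the extensor.
#' @return an object of class `muscle_params`.
#' @seealso [load_preset()] for the packaged "wrist" and "shoulder" sets.
#' @export
muscle_params <- function(f_max, l_ce_opt, l_se_slack, k_se_shape = 3,
                          w_fl = 0.45, v_max = 8, a_hill = 0.25,
                          tau_act = 0.04, tau_deact = 0.06, r = 0.02,
                          sign = 1) {
  p <- list(f_max = f_max, l_ce_opt = l_ce_opt, l_se_slack = l_se_slack,
            k_se_shape = k_se_shape, w_fl = w_fl, v_max = v_max,
            a_hill = a_hill, tau_act = tau_act, tau_deact = tau_deact,
            r = r, sign = sign)
  num <- p[setdiff(names(p), "sign")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))))
    stop("all muscle parameters must be single positive finite numbers")
  if (!sign %in% c(1, -1)) stop("`sign` must be +1 (flexor) or -1 (extensor)")
  if (tau_act > tau_deact) stop("`tau_act` must not exceed `tau_deact`")
  structure(p, class = "muscle_params")
}

#' Joint parameter set
#'
#' @param inertia rotational inertia of the moved segment \[kg m^2\].
#' @param b_passive passive viscous damping \[N m s / rad\].
#' @param theta_neutral neutral joint angle \[rad\]; 0 by convention, and the
#'   angle the passive system returns to.
#' @return an object of class `joint_params`.
#' @export
joint_params <- function(inertia, b_passive = 0, theta_neutral = 0) {
  if (!is.numeric(inertia) || inertia <= 0) stop("`inertia` must be > 0")
  if (!is.numeric(b_passive) || b_passive < 0) stop("`b_passive` must be >= 0")
  structure(list(inertia = inertia, b_passive = b_passive,
                 theta_neutral = theta_neutral),
            class = "joint_params")
}

#' Muscle state
#'
#' The two continuous states of one muscle: activation `a` in \[0, 1\] and
#' contractile-element length `l_ce` > 0 \[m\].
#'
#' @param a activation.
#' @param l_ce CE length \[m\].
#' @export
muscle_state <- function(a, l_ce) {
  if (a < 0 || a > 1) stop("activation must lie in [0, 1]")
  if (l_ce <= 0) stop("`l_ce` must be > 0")
  structure(list(a = a, l_ce = l_ce), class = "muscle_state")
}

#' First-order activation dynamics
#'
#' Rate of change of activation for a neural excitation `u`:
#' `da/dt = (u - a) / tau`, with `tau = tau_act` while excitation exceeds
#' activation (calcium release, fast) and `tau = tau_deact` otherwise
#' (re-uptake, slow).  The fixed point is `a = u`.
#'
#' @param u neural excitation in \[0, 1\].
#' @param a current activation.
#' @param params a [muscle_params()] object.
#' @return da/dt \[1/s\].
#' @export
activation_rate <- function(u, a, params) {
  if (any(u < 0 | u > 1)) stop("excitation `u` must lie in [0, 1]")
  tau <- ifelse(u > a, params$tau_act, params$tau_deact)
  (u - a) / tau
}

#' Active force-length factor
#'
#' Gaussian force-length relation of the contractile element: 1 at the
#' optimal length, symmetric decay of relative width `w_fl`.
#'
#' @param l_ce CE length \[m\] (vectorised).
#' @inheritParams activation_rate
#' @return dimensionless factor in \[0, 1\].
#' @export
force_length <- function(l_ce, params) {
  if (any(l_ce <= 0)) stop("`l_ce` must be > 0")
  exp(-((l_ce / params$l_ce_opt - 1) / params$w_fl)^2)
}

#' Force-velocity factor
#'
#' Hill hyperbola on the concentric side (shortening, `v_ce < 0`): 1 at zero
#' velocity, 0 at `-v_max`.  On the eccentric side a saturating branch rises
#' to a plateau of `r FV_ECC` (1.3) times isometric force, with slope
#' matched to the concentric branch at zero velocity.
#'
#' @param v_ce CE velocity \[m/s\], shortening negative (vectorised).
#' @inheritParams activation_rate
#' @return dimensionless factor in \[0, 1.3\].
#' @export
force_velocity <- function(v_ce, params) {
  vm <- params$v_max * params$l_ce_opt
  a <- params$a_hill
  b <- (FV_ECC - 1) * vm * a / (1 + a)  # slope continuity at v = 0
  out <- numeric(length(v_ce))
  conc <- v_ce < 0
  vc <- pmax(v_ce[conc], -vm)
  out[conc] <- (vm + vc) / (vm - vc / a)
  out[!conc] <- FV_ECC - (FV_ECC - 1) * b / (b + v_ce[!conc])
  out
}

# Inverse of force_velocity: CE velocity producing a required force factor
# `phi`.  phi is clipped to [0, FV_ECC - 0.01] so lengthening velocity stays
# bounded when the required force exceeds the eccentric plateau.
fv_inverse <- function(phi, params) {
  vm <- params$v_max * params$l_ce_opt
  a <- params$a_hill
  b <- (FV_ECC - 1) * vm * a / (1 + a)
  phi <- min(max(phi, 0), FV_ECC - 0.01)
  if (phi <= 1) {
    vm * (phi - 1) / (1 + phi / a)
  } else {
    b * ((FV_ECC - 1) / (FV_ECC - phi) - 1)
  }
}

#' Series-elastic force
#'
#' Exponential tendon force-strain curve: zero at or below slack length,
#' reaching `f_max` at a reference strain of 4 %.
#'
#' @param l_se SE length \[m\] (vectorised).
#' @inheritParams activation_rate
#' @return force \[N\], >= 0.
#' @export
se_force <- function(l_se, params) {
  eps <- (l_se - params$l_se_slack) / params$l_se_slack
  k <- params$k_se_shape
  f <- params$f_max * (exp(k * pmax(eps, 0) / SE_STRAIN_REF) - 1) / (exp(k) - 1)
  ifelse(eps > 0, f, 0)
}

#' Musculotendon length at a joint angle
#'
#' With a constant moment arm, `l_mt = l_ce_opt + l_se_slack - sign * r *
#' theta`: the flexor (`sign = +1`) shortens as the joint flexes (positive
#' `theta`) and the extensor lengthens by the same amount.
#'
#' @param theta joint angle \[rad\], flexion positive.
#' @inheritParams activation_rate
#' @return musculotendon length \[m\].
#' @export
musculotendon_length <- function(theta, params) {
  params$l_ce_opt + params$l_se_slack - params$sign * params$r * theta
}

#' Instantaneous muscle force and contractile-element velocity
#'
#' The SE force at the current CE length is the muscle force (no parallel
#' element).  The CE velocity is the value at which the activation-scaled
#' force-length-velocity product balances that SE force, obtained by
#' inverting the force-velocity relation.  An activation floor (0.005)
#' stands in for minimal tonic drive and keeps the inversion defined for a
#' passive muscle; the required force factor is clipped at the eccentric
#' plateau, which bounds lengthening velocity when the SE force transiently
#' exceeds what the CE can bear.
#'
#' @param state a [muscle_state()] object (or list with `a`, `l_ce`).
#' @param params a [muscle_params()] object.
#' @param l_mt current musculotendon length \[m\].
#' @return list with `force` \[N\] (>= 0) and `v_ce` \[m/s\] (shortening
#'   negative).
#' @export
muscle_force <- function(state, params, l_mt) {
  if (l_mt <= 0) stop("`l_mt` must be > 0")
  f_se <- se_force(l_mt - state$l_ce, params)
  a_eff <- max(state$a, A_MIN)
  fl <- max(force_length(state$l_ce, params), FL_MIN)
  phi <- f_se / (a_eff * params$f_max * fl)
  if (!is.finite(phi))
    stop("muscle equilibrium undefined: non-finite force factor (f_se = ",
         format(f_se), ", a = ", format(state$a), ", l_ce = ",
         format(state$l_ce), ")")
  list(force = f_se, v_ce = fv_inverse(phi, params))
}

#' Joint angular acceleration
#'
#' Newton-Euler balance of the antagonistic pair:
#' `inertia * alpha = r_flex * f_flex - r_ext * f_ext - b_passive * omega +
#' t_external`.
#'
#' @param omega angular velocity \[rad/s\].
#' @param f_flex,f_ext flexor and extensor musculotendon forces \[N\], >= 0.
#' @param t_external external torque \[N m\], flexion positive.
#' @param jp a [joint_params()] object.
#' @param r_flex,r_ext moment arms \[m\].
#' @return angular acceleration \[rad/s^2\].
#' @export
joint_acceleration <- function(omega, f_flex, f_ext, t_external, jp,
                               r_flex, r_ext = r_flex) {
  if (f_flex < 0 || f_ext < 0) stop("muscle forces must be >= 0")
  (r_flex * f_flex - r_ext * f_ext - jp$b_passive * omega + t_external) /
    jp$inertia
}

#' Load a packaged musculoskeletal preset
#'
#' Reads one of the parameter presets shipped with the package
#' (`"wrist"` or `"shoulder"`) from its YAML configuration.  Each preset
#' holds identical flexor and extensor [muscle_params()] (apart from the
#' sign flag), [joint_params()], a reference [reflex_config()] and default
#' protocol amplitudes.  Values are representative of distal (hand/wrist)
#' and proximal (shoulder) human musculature; see the package vignette for
#' how they were chosen.
#'
#' @param name preset name, `"wrist"` or `"shoulder"`, or the path of a YAML
#'   file with the same structure.
#' @return a list of class `dystonia_preset` with elements `name`, `flexor`,
#'   `extensor`, `joint`, `reflex`, `protocol`.
#' @export
load_preset <- function(name = c("wrist", "shoulder")) {
  if (length(name) == 1 && file.exists(name)) {
    path <- name
  } else {
    name <- match.arg(name)
    path <- system.file("extdata", paste0("preset-", name, ".yaml"),
                        package = "crpsdystonia", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  m <- cfg$muscle
  mk <- function(sgn) muscle_params(
    f_max = m$f_max, l_ce_opt = m$l_ce_opt, l_se_slack = m$l_se_slack,
    k_se_shape = m$k_se_shape, w_fl = m$w_fl, v_max = m$v_max,
    a_hill = m$a_hill, tau_act = m$tau_act, tau_deact = m$tau_deact,
    r = m$r, sign = sgn)
  rx <- cfg$reflex
  entry <- function() reflex_entry(
    k_p = rx$k_p, k_v = rx$k_v, k_f = rx$k_f,
    tau_p = rx$tau_p, tau_v = rx$tau_v, tau_f = rx$tau_f)
  structure(list(
    name = cfg$name,
    flexor = mk(1), extensor = mk(-1),
    joint = joint_params(cfg$joint$inertia, cfg$joint$b_passive),
    reflex = reflex_config(flexor = entry(), extensor = entry()),
    protocol = list(t_force = cfg$protocol$t_force,
                    u_voluntary = cfg$protocol$u_voluntary)
  ), class = "dystonia_preset")
}
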