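# Proprioceptive reflex feedback: three pathways per muscle, each with a
# gain, an additive offset and a neural conduction delay.
#
#   position  - muscle spindle, type II afferents, responds to stretch
#               beyond neutral length, lengthening only (half-wave
#               rectified);
#   velocity  - muscle spindle, type Ia afferents, responds to lengthening
#               rate only (half-wave rectified);
#   force     - Golgi tendon organ, type Ib afferents, responds to muscle
#               force, active during both shortening and lengthening.
#
# All three pathways EXCITE the contractile element of their own muscle.
# For the force pathway this is a disinhibition assumption: physiological
# Ib feedback is inhibitory, but reduced central inhibition in CRPS is
# modelled by letting the net loop act excitatorily.

PATHWAYS <- c("position", "velocity", "force")
SCENARIOS <- c("reference", "increased_sensitivity", "imbalanced_sensitivity",
               "imbalanced_offset")

#' One muscle's reflex feedback settings
#'
#' @param k_p,k_v,k_f pathway gains (excitation per unit normalized stretch,
#'   stretch rate and force); >= 0.
#' @param e_p,e_v,e_f additive pathway offsets (tonic excitation); >= 0.
#' @param tau_p,tau_v,tau_f pathway delays \[s\]; > 0.
#' @return a list of class `reflex_entry`.
#' @export
reflex_entry <- function(k_p = 0, k_v = 0, k_f = 0,
                         e_p = 0, e_v = 0, e_f = 0,
                         tau_p = 0.03, tau_v = 0.03, tau_f = 0.03) {
  e <- list(k_p = k_p, k_v = k_v, k_f = k_f,
            e_p = e_p, e_v = e_v, e_f = e_f,
            tau_p = tau_p, tau_v = tau_v, tau_f = tau_f)
  if (any(unlist(e[1:6]) < 0))
    stop("reflex gains and offsets must be >= 0 (all pathways excitatory)")
  if (any(unlist(e[7:9]) <= 0)) stop("reflex delays must be > 0")
  structure(e, class = "reflex_entry")
}

#' Reflex configuration for the antagonistic pair
#'
#' @param flexor,extensor [reflex_entry()] objects.
#' @return a list of class `reflex_config`.
#' @export
reflex_config <- function(flexor, extensor) {
  stopifnot(inherits(flexor, "reflex_entry"), inherits(extensor, "reflex_entry"))
  structure(list(flexor = flexor, extensor = extensor),
            class = "reflex_config")
}

#' Aberrant reflex scenario specification
#'
#' Three aberrations of a normal reflex configuration are modelled, each
#' applied to one feedback pathway:
#' * `increased_sensitivity` ("hyperreflexia"): the pathway gain is
#'   multiplied by `magnitude` in *both* muscles;
#' * `imbalanced_sensitivity`: the gain is multiplied in the *agonist* only;
#' * `imbalanced_offset`: the pathway offset of the agonist only is set to
#'   `magnitude` (a tonic drive independent of afferent input).
#' `reference` leaves the configuration unchanged and ignores `pathway` and
#' `magnitude`.
#'
#' @param scenario one of `"reference"`, `"increased_sensitivity"`,
#'   `"imbalanced_sensitivity"`, `"imbalanced_offset"`.
#' @param pathway one of `"position"`, `"velocity"`, `"force"`.
#' @param magnitude gain multiplier (> 1) for the sensitivity scenarios, or
#'   offset level (> 0) for the offset scenario.
#' @param agonist which muscle carries the aberration in the imbalanced
#'   scenarios; `"flexor"` (default, matching the dominant clinical flexion
#'   pattern) or `"extensor"`.
#' @return a list of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario, pathway = "force", magnitude = 1,
                          agonist = "flexor") {
  if (!scenario %in% SCENARIOS)
    stop("unknown scenario '", scenario, "'; expected one of: ",
         paste(SCENARIOS, collapse = ", "))
  if (!pathway %in% PATHWAYS)
    stop("unknown pathway '", pathway, "'; expected one of: ",
         paste(PATHWAYS, collapse = ", "))
  agonist <- match.arg(agonist, c("flexor", "extensor"))
  if (scenario %in% c("increased_sensitivity", "imbalanced_sensitivity") &&
      magnitude < 1)
    stop("sensitivity scenarios need `magnitude` >= 1 (1 is the identity)")
  if (scenario == "imbalanced_offset" && magnitude <= 0)
    stop("offset scenario needs `magnitude` > 0")
  structure(list(scenario = scenario, pathway = pathway,
                 magnitude = magnitude, agonist = agonist),
            class = "scenario_spec")
}

#' Muscle-spindle position signal (type II)
#'
#' Half-wave rectified: responds only to lengthening beyond the neutral
#' length, zero for a shortened muscle.
#'
#' @param stretch normalized CE stretch beyond neutral length (vectorised).
#' @return non-negative signal.
#' @export
spindle_position_signal <- function(stretch) {
  stopifnot(all(is.finite(stretch)))
  pmax(stretch, 0)
}

#' Muscle-spindle velocity signal (type Ia)
#'
#' Half-wave rectified: responds only to lengthening, zero during
#' shortening.
#'
#' @param stretch_rate normalized lengthening rate (vectorised).
#' @return non-negative signal.
#' @export
spindle_velocity_signal <- function(stretch_rate) {
  stopifnot(all(is.finite(stretch_rate)))
  pmax(stretch_rate, 0)
}

#' Golgi tendon organ force signal (type Ib)
#'
#' Muscle force normalized by the maximal isometric force.  Bidirectional
#' with respect to length change: the signal depends on force alone, so it
#' is identical during shortening and lengthening at equal force.
#'
#' @param force muscle force \[N\], >= 0 (vectorised).
#' @param f_max maximal isometric force \[N\].
#' @return normalized signal >= 0.
#' @export
gto_force_signal <- function(force, f_max) {
  if (any(force < 0)) stop("`force` must be >= 0")
  force / f_max
}

#' Reflex excitation of one muscle
#'
#' Linear combination of the three delayed pathway signals:
#' `k_p * sig_p + e_p + k_v * sig_v + e_v + k_f * sig_f + e_f`.  Each signal
#' must be the value of its pathway `tau_p`/`tau_v`/`tau_f` seconds in the
#' past.  The total neural drive of the muscle is
#' `clip(u_voluntary + reflex excitation, 0, 1)`.
#'
#' @param delayed_stretch,delayed_rate,delayed_force pathway signals read at
#'   their own delays (already rectified/normalized).
#' @param entry a [reflex_entry()].
#' @return excitation contribution, >= 0.
#' @export
reflex_excitation <- function(delayed_stretch, delayed_rate, delayed_force,
                              entry) {
  entry$k_p * delayed_stretch + entry$e_p +
    entry$k_v * delayed_rate + entry$e_v +
    entry$k_f * delayed_force + entry$e_f
}

#' Apply an aberrant scenario to a reference reflex configuration
#'
#' Pure transformation: the base configuration is not modified.  See
#' [scenario_spec()] for what each scenario does.  Enumerating the three
#' aberrant scenarios over the three pathways yields the nine aberrant
#' conditions simulated by [run_battery()].
#'
#' @param base the reference [reflex_config()].
#' @param spec a [scenario_spec()].
#' @return a new [reflex_config()].
#' @export
apply_scenario <- function(base, spec) {
  stopifnot(inherits(base, "reflex_config"), inherits(spec, "scenario_spec"))
  if (spec$scenario == "reference") return(base)
  gain_key <- c(position = "k_p", velocity = "k_v", force = "k_f")[spec$pathway]
  off_key <- c(position = "e_p", velocity = "e_v", force = "e_f")[spec$pathway]
  out <- base
  targets <- switch(spec$scenario,
    increased_sensitivity = c("flexor", "extensor"),
    imbalanced_sensitivity = spec$agonist,
    imbalanced_offset = spec$agonist)
  for (m in targets) {
    if (spec$scenario == "imbalanced_offset") {
      out[[m]][[off_key]] <- spec$magnitude
    } else {
      out[[m]][[gain_key]] <- out[[m]][[gain_key]] * spec$magnitude
    }
  }
  out
}

# Condition label used by run_battery and the score table.
condition_label <- function(spec) {
  if (spec$scenario == "reference") "reference"
  else paste(spec$scenario, spec$pathway, sep = "_")
}
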