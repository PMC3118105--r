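---
title: "An antagonistic muscle pair with aberrant proprioceptive reflexes: modelling fixed dystonia in CRPS"
author: "crpsdystonia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An antagonistic muscle pair with aberrant proprioceptive reflexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crpsdystonia)
```

## The question the model addresses

Roughly a quarter of patients with complex regional pain syndrome (CRPS)
develop *fixed dystonia*: a sustained abnormal posture of the affected limb,
overwhelmingly flexion of the distal joints (fingers, wrist; toes, ankle).
One candidate mechanism is aberrant proprioceptive reflex gain.  Spinal
feedback reaches a muscle through three pathways: muscle-spindle type II
afferents (muscle length, "position"), muscle-spindle type Ia afferents
(lengthening velocity), and Golgi tendon organ (GTO) type Ib afferents
(muscle force).  If central disinhibition scales these loops up — or biases
them toward one muscle of an antagonistic pair — which pathway, disturbed in
which way, produces behaviour that actually looks like fixed dystonia?

This package implements a minimal neuromechanical test of that question: two
identical antagonistic Hill-type muscles acting on a single hinge joint
(hand or upper-arm inertia), each muscle excited by its own delayed
position, velocity and force feedback.  A reference configuration with
stable, normal reflexes is perturbed in three ways, each applied to each
pathway (nine aberrant conditions):

* **increased sensitivity** — the pathway gain is multiplied in *both*
  muscles (hyperreflexia);
* **imbalanced sensitivity** — the gain is multiplied in the *agonist* only;
* **imbalanced offset** — a tonic output offset is added to the agonist's
  pathway only.

Every condition runs the same 20 s protocol — 5 s of constant external
torque, 5 s rest, 5 s of constant voluntary drive to the agonist, 5 s rest —
and is scored 0–5 against five clinical characteristics of fixed dystonia:
abnormal posture, sustained contraction, increased stiffness, worsening with
activity, and loss of voluntary control.

## Model structure

### Muscle

Each muscle is a Hill-type musculotendon: a contractile element (CE) in
series with an exponential series-elastic element (SE), no parallel-elastic
element (see *Design choices*).  The CE force is
$F_{ce} = a\, F_{max}\, f_l(\ell_{ce})\, f_v(v_{ce})$ with

* activation $a$ following first-order excitation dynamics
  $\dot a = (u - a)/\tau$, with $\tau_{act} = 40$ ms on the way up and
  $\tau_{deact} = 90$ ms on the way down;
* a Gaussian force–length factor $f_l = \exp(-((\ell_{ce}/\ell_{opt} -
  1)/w)^2)$, width $w = 0.38$;
* a Hill force–velocity hyperbola on the concentric side (zero force at
  $-v_{max}$, $v_{max} = 8\,\ell_{opt}/s$, curvature $a_h = 0.25$) and a
  slope-matched saturating eccentric branch with a plateau at $1.3\,
  F_{max}$;
* an exponential SE force–strain curve reaching $F_{max}$ at 4 % strain.

The CE velocity is obtained by inverting the force–velocity relation at the
current SE force (the standard DAE reduction), so each muscle carries
exactly two continuous states, $a$ and $\ell_{ce}$.  Two numerical floors
keep the inversion defined: activation is floored at 0.005 in the inversion
(a minimal tonic drive) and the required force factor is clipped at the
eccentric plateau, which bounds lengthening velocity when the SE transiently
carries more force than the CE can bear.

### Joint

A single degree of freedom with constant moment arms:
$I\ddot\theta = r F_{flex} - r F_{ext} - b\dot\theta + T_{ext}$, flexion
positive.  The musculotendon length of the flexor is
$\ell_{mt} = \ell_{opt} + \ell_{slack} - r\theta$ (and $+ r\theta$ for the
extensor), so the pair's length changes are equal and opposite.

### Reflexes

Each muscle's neural drive is
$u = \mathrm{clip}\big(u_{vol} + k_p\,s_p(t-\tau_p) + e_p + k_v\,s_v(t-\tau_v)
+ e_v + k_f\,s_f(t-\tau_f) + e_f,\ 0,\ 1\big)$, with

* $s_p$ = CE stretch beyond the neutral-rest length, normalized by
  $\ell_{opt}$, half-wave rectified (spindles respond to lengthening only);
* $s_v$ = normalized lengthening rate, half-wave rectified;
* $s_f$ = muscle force normalized by $F_{max}$, bidirectional in length
  change because force is.

All three pathways are *excitatory*, including the GTO pathway.
Physiological Ib feedback is inhibitory; modelling it as net-excitatory is a
deliberate disinhibition assumption, representing the loss of central
inhibition documented in CRPS.  This sign choice is what makes amplified
force feedback a positive feedback loop — the mechanism behind the dystonic
latch below.  Reflex adaptation is deliberately absent: gains are constant
across all protocol phases, so external force and voluntary movement both
elicit reflexes.

## Parameters

The two presets, `wrist` (distal) and `shoulder` (proximal), live in YAML
files under `inst/extdata/` and are loaded with `load_preset()`.  No
numerical parameter values for the original model are published, so the
presets are *representative*, chosen at physiological orders of magnitude
and then calibrated — as the scoring thresholds explicitly allow — so that
the reference configuration is stable, resists the external torque, and
returns to neutral within ~2 s of each phase end:

| parameter | wrist | shoulder | units |
|---|---|---|---|
| $F_{max}$ | 150 | 500 | N |
| $\ell_{opt}$ / $\ell_{slack}$ | 0.06 / 0.20 | 0.07 / 0.20 | m |
| $r$ (moment arm) | 0.02 | 0.04 | m |
| $I$ | 0.005 | 0.25 | kg m² |
| $b$ (viscous) | 0.07 | 0.7 | N m s/rad |
| $k_p$, $k_v$, $k_f$ | 1.4, 0.08, 0.5 | 1.4, 0.08, 0.5 | — |
| reflex delays | 30 | 20 | ms |
| $T_{ext}$, $u_{vol}$ | 0.8 N m, 0.3 | 4.0 N m, 0.3 | |

Delays are longer distally than proximally, reflecting conduction distance.
Both presets keep a similar tendon-slack-to-fiber-length ratio.  That ratio
matters more than it looks: under strong co-contraction both contractile
elements shorten by the tendon stretch, onto the ascending limb of the
force-length curve, and the *difference* of the two force-length factors is
what gives the co-contracted joint its stiffness.  A proximal preset with a
much shorter relative tendon would leave the fully co-contracted joint with
almost no differential stiffness, and the balanced force-feedback condition
would drift under external torque instead of exhibiting rigidity.
The battery defaults are a ×4 gain multiplier for the sensitivity scenarios
and a 0.025 offset for the offset scenario; the severity sweep uses ×2, ×3,
×4 (beyond roughly ×6 the imbalanced joint leaves the physical angle bound
and the run is flagged unstable rather than scored).

## Numerical integration

The coupled system is a delay differential equation.  The integrator is
explicit fixed-step RK4 with the six continuous states; delayed pathway
signals are recorded on the step grid and read back at exact grid multiples
(delays are validated to be integer multiples of the step), with the RK4
midpoint stages using the mean of the step-start and step-end delayed
drives.  History before $t=0$ is pinned at the neutral-rest equilibrium of
the *reference* configuration — found by root-solving the tone/force-feedback
balance — so all ten conditions start from the identical resting state and
the spindle "neutral length" is exactly the resting CE length.

The default step is $2.5\times10^{-4}$ s.  A coarser 1 ms step would
comfortably resolve the delays, but the protocol's square torque onset
drives a fast transient through the model's non-smooth events (tendon
slack/taut transitions, the eccentric force cap), and at 1 ms that transient
carries an error of order $10^{-2}$ rad against a $10^{-5}$ s Euler
reference; at $2.5\times10^{-4}$ s the whole-trajectory error is below
$10^{-4}$ rad.  The test suite holds the integrator to that standard against
an independently written forward-Euler oracle.  A 20 s condition takes well
under a second, the full 10-condition battery a couple of seconds.

Runs that leave $|\theta| < 3$ rad or produce non-finite state are flagged
`unstable` in their metadata (remaining samples `NA`) instead of raising an
error, so unstable aberrant conditions remain reportable and score the flags
their finite prefix supports.

## What the aberrant conditions do

With the default presets the battery reproduces a consistent qualitative
map, identical for the wrist and shoulder parameter sets:

* **Increased position or velocity sensitivity** destabilizes the
  delay-coupled loop: fast oscillation (five or more velocity
  zero-crossings within 2 s) without any abnormal resting posture.
* **Increased force sensitivity** turns both muscles' force feedback into a
  self-sustaining positive loop.  Because it is balanced, the joint stays at
  neutral, but both muscles co-contract strongly: deflection under the
  external torque and movement under voluntary drive collapse — rigidity.
* **Imbalanced offset** adds tonic drive to the flexor: the joint settles
  in a mildly flexed abnormal posture, but stiffness, co-contraction and
  the voluntary response remain essentially normal.
* **Imbalanced force sensitivity** is the only condition scoring 5/5.  The
  flexor's amplified excitatory force feedback latches: any flexor force is
  amplified into drive, which shortens the flexor until its force–length
  factor caps the loop ($f_l = 1/(k_f m)$, with $m$ the multiplier).  The
  stretched extensor's position feedback balances the latch at a fixed
  flexed angle, with high agonist *and* antagonist torques
  (co-contraction), reduced deflection under torque, deviation deepening
  during voluntary activity, and a strongly reduced voluntary excursion.
  The latched angle grows monotonically with the multiplier — the degree of
  imbalance sets the severity of the posture.

## Scoring: operationalizing the five characteristics

No numeric criteria for the five clinical characteristics are published;
`score_thresholds()` documents one defensible operationalization, applied
relative to the reference run on the same grid (windows scale with the
phase length; times below are for 5 s phases):

* *abnormal posture* — |mean angle over 19–20 s| > 0.05 rad;
* *sustained contraction* — the **less** active muscle's mean activation
  over the final rest exceeds the reference's by > 0.05 (keying on the
  minimum of the pair makes this a co-contraction detector);
* *increased stiffness* — the torque-phase deflection, measured from the
  run's own final resting posture, is < 0.5 × the reference's deflection;
* *worsening with activity* — an abnormal posture is present *and* the
  deviation during the voluntary phase exceeds the run's own resting
  posture by > 0.02 rad;
* *loss of voluntary control* — the voluntary-phase excursion (settled
  voluntary mean minus the preceding resting posture) is < 0.5 × the
  reference's.

Two of these deserve comment.  **Worsening with activity** is anchored on
the abnormal posture and measured *during* activity rather than as a
rest-to-rest difference.  The reason is structural: the model's
force-feedback latch has a unique attractor (the force–length factor is
maximal at the neutral CE length, so the latch's loop gain is highest at
rest and the latched equilibrium is unique), which makes both rest phases
settle to the *same* angle whenever the latch is deep enough to also
produce stiffness and loss of voluntary control.  What the model does show —
and what the clinical label describes — is the dystonic deviation deepening
whenever the limb is active, and that is what is scored.  The
abnormal-posture anchor keeps the reference at 0/5: a normal voluntary
excursion from neutral is not a worsening of anything.

**Increased stiffness** is measured against the run's own resting posture
because the dystonic run's meaningful baseline is the posture it holds, not
the neutral angle it briefly occupied at $t = 0$.

Thresholds are calibrated (and documented here) such that the reference
scores 0 and the qualitative map above holds; all are config-overridable
and are reported alongside every score table.

## The clinical posture analytics

The unit of analysis is the limb: one record per limb with a posture
category per joint (arms: fingers, wrist, elbow, shoulder; legs: toes,
ankle, knee, hip) and a Burke–Fahn–Marsden severity grade.
`combination_table()` maps each dystonic limb to four common-pattern
indicators (finger/wrist/elbow flexion + shoulder adduction; toe plantar
flexion, ankle plantar flexion and/or inversion, knee flexion, hip internal
rotation), tabulates the distinct combinations, and counts rare-pattern and
non-dystonic limbs separately.  `fixture_cohort()` rebuilds, limb by limb,
the exact published combination counts (118 arms over ten patterns, 113
legs over ten patterns), so the marginal totals — 116/41/38/12 for the arm
joints, 55/100/32/11 for the leg joints — are reproduced by computation
rather than assertion.

`lr_symmetry_test()` is a two-sided Fisher exact test of side ×
dystonia-present, computed by full hypergeometric enumeration: all tables
with the observed margins are enumerated and the probabilities of those no
more probable than the observed table are summed (with a $10^{-7}$ relative
slack against floating-point ties, the common convention).  A zero margin
yields p = 1 with a warning.  `proximal_distal_containment()` checks the
distal-to-proximal structure of the published cohort — every
shoulder-involved arm has finger involvement, every hip-involved leg an
affected ankle — and returns violators.

## The synthetic cohort generator

Raw per-patient data are not published; only aggregate tables are.  The
generator (`generate_cohort()`) emulates a cohort with that aggregate
structure so every clinical operation is testable end-to-end:

* each patient contributes two arms and two legs; each limb is affected
  independently with a per-type probability calibrated so the expected
  bilateral fraction among affected patients matches the published 46/77
  (arms) and 37/77 (legs) — under side-independence $P(\text{both}\mid\geq
  1) = q/(2-q)$, giving $q = 92/123$ and $74/114$;
* an affected limb draws a rare posture with probability 5/123 (arms) or
  1/114 (legs), otherwise one of the ten common combination patterns with
  probabilities proportional to the published counts;
* severity is assigned per patient: a maximum grade is drawn from the
  published per-patient mix (11.8 / 41.2 / 24.7 / 22.3 % for slight / mild /
  moderate / severe), given to one randomly chosen dystonic limb, and the
  patient's other dystonic limbs draw uniformly from the grades up to that
  maximum.  Drawing severity independently per limb would inflate the
  per-patient *maximum* toward "severe", so the per-patient construction is
  what makes `severity_summary()` recover the published mix.

All sampling flows from the single seed in the spec; the cohort is a
deterministic function of the spec and the caller's RNG state is left
untouched.

What the generator deliberately does **not** model: correlations between a
patient's arm and leg involvement, disease progression or the temporal
spread of dystonia, any association between pattern and severity, and
demographic structure (age, sex, disease duration).  Tests passing on
synthetic cohorts therefore validate the *analytics* (tables, marginals,
exact test, severity summary) and the stated aggregate structure — they are
not evidence about unpublished patient-level relationships.

## Worked example

```{r example, eval = FALSE}
preset <- load_preset("wrist")
battery <- run_battery(preset)
score_battery(battery)

cohort <- generate_cohort(default_cohort_spec(n_patients = 200, seed = 7))
marginal_counts(combination_table(cohort, "arm"))
lr_symmetry_test(cohort, "arm")$p.value
```

## Known limitations

* Parameter presets are representative, not a reconstruction of the
  original model's (unpublished) values; conclusions are qualitative.
* The passive pair (zero reflex gains) is neutrally — not asymptotically —
  stable: with symmetric resting tone the contractile elements yield and
  re-equilibrate at any angle, so the return to neutral is a property of
  the reference *reflexes*.  A parallel-elastic element would restore
  passive stiffness at the cost of a second length-dependent force; the
  simpler structure suffices for every behaviour studied here.
* Moment arms are constant, the joints are frictionless hinges, and there
  is no fusimotor drive, no Renshaw inhibition, no reflex adaptation and no
  muscle fatigue.
* Square input phases excite the model's non-smooth events; the step size
  below is chosen for that, and coarser steps can destabilize the strongly
  latched conditions numerically.
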