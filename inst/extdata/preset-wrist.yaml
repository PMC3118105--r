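# Distal (wrist/hand) musculoskeletal preset.
# Representative order-of-magnitude values for an antagonistic wrist
# flexor/extensor pair acting on hand inertia; SI units throughout.
# Reflex delays are longer than in the proximal (shoulder) preset, as
# neural conduction distance is greater distally.  Reference reflex gains
# are calibrated so the reference simulation is stable, resists the
# external torque, and returns to the neutral posture within two seconds
# of each phase end.
name: wrist
muscle:
  f_max: 150.0        # N
  l_ce_opt: 0.06      # m
  l_se_slack: 0.20    # m
  k_se_shape: 3.0
  w_fl: 0.38
  v_max: 8.0          # l_ce_opt / s
  a_hill: 0.25
  tau_act: 0.04       # s
  tau_deact: 0.09     # s
  r: 0.02             # m
joint:
  inertia: 0.005      # kg m^2
  b_passive: 0.07     # N m s / rad
reflex:
  k_p: 1.4
  k_v: 0.08
  k_f: 0.5
  tau_p: 0.03         # s
  tau_v: 0.03
  tau_f: 0.03
protocol:
  t_force: 0.8        # N m, flexion-assisting
  u_voluntary: 0.3
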