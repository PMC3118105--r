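# Proximal (shoulder) musculoskeletal preset.
# Representative order-of-magnitude values for an antagonistic shoulder
# muscle pair acting on upper-arm inertia; SI units throughout.
# Shorter reflex delays than the distal (wrist) preset; same reference
# reflex gains, with torque and damping scaled to the heavier segment.
name: shoulder
muscle:
  f_max: 500.0        # N
  l_ce_opt: 0.07      # m
  l_se_slack: 0.20    # m
  k_se_shape: 3.0
  w_fl: 0.38
  v_max: 8.0          # l_ce_opt / s
  a_hill: 0.25
  tau_act: 0.04       # s
  tau_deact: 0.09     # s
  r: 0.04             # m
joint:
  inertia: 0.25       # kg m^2
  b_passive: 0.7      # N m s / rad
reflex:
  k_p: 1.4
  k_v: 0.08
  k_f: 0.5
  tau_p: 0.02         # s
  tau_v: 0.02
  tau_f: 0.02
protocol:
  t_force: 4.0        # N m, flexion-assisting
  u_voluntary: 0.3
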