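# example cohort: one patient with a dystonic right arm (finger and wrist
# flexion, mild), a non-dystonic left arm and a dystonic right leg
patient_id,side,limb,fingers,wrist,elbow,shoulder,toes,ankle,knee,hip,severity
p01,right,arm,flexion,flexion,none,none,,,,,mild
p01,left,arm,none,none,none,none,,,,,none
p01,right,leg,,,,,plantar_flexion,plantar_flexion_inversion,none,none,moderate
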