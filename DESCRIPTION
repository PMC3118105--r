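Package: crpsdystonia
Title: Neuromuscular Modelling and Posture-Pattern Analysis of Fixed
    Dystonia in Complex Regional Pain Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates an antagonistic Hill-type muscle pair acting on a
    single joint with delayed proprioceptive feedback from muscle spindles
    (position and velocity) and Golgi tendon organs (force), and evaluates
    how aberrant reflex settings (increased sensitivity, imbalanced
    sensitivity, imbalanced offset) reproduce the clinical characteristics
    of fixed dystonia in complex regional pain syndrome (CRPS).  Scores
    each simulated condition against five clinical criteria (abnormal
    posture, sustained contraction, increased stiffness, worsening with
    activity, loss of voluntary control).  Also provides per-limb posture
    record handling, arm and leg posture-combination tables with marginal
    counts, a distal-to-proximal containment check, an exact left/right
    symmetry test, and a seeded synthetic cohort generator that emulates
    the posture-pattern and severity structure reported for CRPS cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
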