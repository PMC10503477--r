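Package: pigletgait
Title: Dynamic-Similarity Analysis of Early Piglet Locomotor Maturation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying early locomotor maturation in low- and
    normal-birth-weight (SGA and AGA) piglets from gait recordings.
    Provides dynamic-similarity (Froude) normalization of spatiotemporal
    gait variables using midstance hip height as the length scale, Fourier
    series decomposition of cyclic limb joint kinematics into posture
    (mean angle, amplitude) and coordination (principal component)
    descriptors, nonparametric permutation-based statistical parametric
    mapping of stance-normalized ground reaction force curves, muscle
    force-generating capacity from physiological cross-sectional areas,
    Huxley allometric power-law fits of body-part masses, and Bayesian
    inverse prediction of body mass, size and age from stride features.
    A seeded synthetic cohort generator emulates the statistical structure
    of neonatal piglet gait so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
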