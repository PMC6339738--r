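Package: gripangle
Title: Finger Joint Flexion Angles During Cylinder Gripping from Bone-Model Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures finger joint flexion angles (DIP, PIP, MP of the four
    fingers) during power grip of cylinders from three-dimensional bone-model
    landmarks: eight-point surface rings on each phalanx end give end-center
    estimates, base-to-head direction vectors give bone axes, and the angle
    between consecutive axes gives the joint flexion angle.  Includes a
    synthetic kinematic hand generator (capsule bone meshes, forward-kinematic
    finger chains, a deterministic cylinder-wrap grip solver, and a cohort
    simulator parameterized by published cell means), the coupling ratio
    DIP/PIP, summary tables, and a from-scratch balanced repeated-measures
    factorial ANOVA with Mauchly's sphericity test, Greenhouse-Geisser
    correction, simple main effects and Bonferroni pairwise comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
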