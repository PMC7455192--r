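Package: pathintlab
Title: Path Integration Task Simulation, Behavioral Metrics, and
    Grid-Code fMRI Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying path integration in virtual navigation
    experiments of the "apple game" type: balanced trial-set generation on
    an 8 x 8 location grid inside a circular arena, a seeded
    dead-reckoning agent simulator that produces cohort-scale trajectory
    logfiles with distance-dependent error accumulation and cue-dependent
    correction, per-trial homing-error metrics and performance transforms,
    APOE genotype and cohort statistics, declarative linear mixed-model
    designs with type-II tests and Tukey-adjusted quintile post-hocs, a
    grid-cell-population BOLD simulator, a hexadirectional (sixfold)
    pattern-similarity pipeline with permutation uniformity tests, and
    parametric-modulator GLM designs for integrated path and goal
    proximity.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    emmeans,
    lme4,
    stats,
    utils
Suggests:
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
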