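Package: gaitersp
Title: Gait-Cycle Electrocortical Dynamics During Uneven Terrain Walking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of mobile EEG recorded during treadmill
    walking on uneven terrain. Provides a synthetic multi-subject gait-EEG
    generator with known ground truth; insole-force gait event detection and
    gait variability metrics; an EEG cleaning chain (zero-phase FIR filters,
    sliding-window line-noise regression, robust channel and window rejection,
    canonical-correlation reference cleaning, ICA) with equivalent-dipole
    component selection and k-means dipole clustering; gait-cycle time-warped
    Morlet event-related spectral perturbations, spectral-PCA muscle-artifact
    correction, aperiodic/periodic spectral parameterization, band power and
    intra-stride peak-to-peak fluctuation metrics; and the statistical layer
    (bootstrap and permutation significance masking with FDR control,
    cluster-based permutation tests, and terrain-by-age linear mixed models
    with walking speed as covariate).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    lme4,
    lmerTest,
    emmeans
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
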