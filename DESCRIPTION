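Package: abrstab
Title: Trial-by-Trial Neural Stability of Auditory Brainstem Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies trial-by-trial neural stability of click- and
    speech-evoked auditory brainstem responses (ABR). Provides a synthetic
    sweep and cohort generator with known ground truth, offline preprocessing
    (zero-phase bandpass filtering, amplitude-based artifact rejection,
    low-noise sweep accumulation), polarity- and channel-balanced subaverage
    construction, component-windowed Pearson stability with Fisher transform,
    spectral F-test response detection against the noise floor, prestimulus
    RMS noise metrics, trait-table ingestion (AQ, SRS-2), and the inferential
    chain linking stability to trait scores: nested linear mixed models with
    sum-coded components, BIC selection, Satterthwaite tests, Tukey-adjusted
    component contrasts, marginal and conditional R-squared, subscale
    likelihood-ratio tests, repeated-measures ANOVA with Greenhouse-Geisser
    correction, and variance inflation factors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    lme4,
    lmerTest,
    emmeans,
    car,
    jsonlite,
    data.table
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'template.R'
    'simulate.R'
    'sweep-store.R'
    'preprocess.R'
    'stability.R'
    'detection.R'
    'traits.R'
    'lmm.R'
    'anova-tools.R'
    'pipeline.R'
    'abrstab-package.R'
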