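Package: oxydrift
Title: Cerebral Oxygenation Drift Analysis for Exercise fNIRS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for functional near-infrared spectroscopy
    (fNIRS) recordings acquired during exhaustive exercise. Provides channel
    quality control (Welch-spectrum cardiac-peak validation, scalp-coupling
    index screening, optode-headset shift detection from motion-capture
    markers), motion-artifact correction by wavelet coefficient fencing,
    zero-phase lowpass filtering, regression of the extracerebral systemic
    component against a photoplethysmographic pulse trace, and the
    oxygenation-decline metrics computed per region of interest: the decline
    point D (argmax of a polynomial fit to the hemodynamic response, as a
    percentage of the supra-threshold exercise phase), the activation slope
    beta, the baseline-to-end delta, and a continuous two-segment (breakpoint)
    linear alternative compared by AIC/BIC. An inferential layer implements
    z-score outlier screening with iterative winsorization, ordered quantile
    normalization, repeated-measures ANOVA with Mauchly/Greenhouse-Geisser
    handling, the Friedman test with Kendall's W, paired equivalence testing
    (TOST), and paired t-test power planning including small-telescopes
    smallest-effect-size-of-interest computations. A synthetic-data module
    generates recordings, pulse traces, marker trajectories and cohort outcome
    tables with known ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
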