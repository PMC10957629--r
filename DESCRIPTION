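Package: postprandial
Title: Postprandial Amino Acid Response Analysis for Crossover Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of postprandial amino acid (and other nutrient)
    time-course data from crossover intervention trials.  Fits
    four-parameter Wood curves to each participant x intervention x
    analyte series by multi-start bounded nonlinear least squares,
    extracts area under the curve (via the lower incomplete gamma
    function), peak height and time-to-maximum analytically, curates
    curve parameters and parameters of interest against plausible
    ranges, imputes non-responder values from the quantile spread of the
    raw data, and compares test interventions against a reference via
    linear mixed models with ratio or difference contrasts
    (Kenward-Roger or Satterthwaite degrees of freedom).  Includes a
    synthetic crossover-study generator with known ground truth,
    visualization (time-course panels, PCA score plots, dot plots,
    forest plots) and a scripted pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    lattice,
    lme4,
    lmerTest,
    pbkrtest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    optparse,
    jsonlite
Config/testthat/edition: 3
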