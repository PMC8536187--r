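Package: repleteaudit
Title: Audit of Electrolyte Repletion Practice in ICU Event Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to audit electrolyte (potassium, magnesium, phosphate)
    repletion practice in intensive-care event streams shaped like the
    MIMIC-III clinical database. Implements cohort construction with a full
    attrition log, 24-hour time-window linkage of serum laboratory values to
    repletion orders with a three-scenario classification, nominal
    reference-range interpretation tables, repletion-effectiveness statistics
    (pooled t, Cohen's d, ordinary least squares regression, one-way ANOVA),
    circadian workflow and latency analyses, and a synthetic event-stream
    generator with planted, analytically known ground truth for end-to-end
    validation without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
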