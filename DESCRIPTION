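Package: accelrel
Title: Reliability of Accelerometer-Measured Sedentary Time and Physical Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying how many days of accelerometer monitoring are
    needed to obtain reliable estimates of sedentary time and physical activity.
    Reduces epoch-level activity counts to daily and weekly summaries under
    configurable non-wear detection, intensity cut-points and wear-time validity
    criteria; partitions variance with one-way random-effect and wear-adjusted
    mixed models; and derives single-day and week-by-week reliability statistics
    (intraclass correlations, Spearman-Brown days-needed projections, standard
    errors of measurement, 95% limits of agreement, percentage typical error) plus
    Bland-Altman week-by-week agreement and weekday/weekend contrasts. Includes a
    seeded synthetic cohort generator with known ground-truth variance structure
    so the full pipeline can be exercised and validated without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lme4,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
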