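Package: ceatopo
Title: Peri-Event Calcium Imaging Statistics and Amygdala Circuit Topography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the rostro-caudal topography of central-amygdala
    neuron populations: peri-event calcium-trace normalisation (deltaF/F and
    baseline z-scores), responsive-neuron classification by Wilcoxon signed-rank
    and normalised area-under-curve criteria, linear and sigmoid tuning fits with
    bootstrap model comparison, and tracing-topography statistics
    (expression-cutoff region filtering, input-connectivity correlation
    clustering, anterior-posterior shuffle permutation nulls, local-connectivity
    and projection-bias regressions). Includes seeded synthetic-data generators
    with planted ground truth for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    withr,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
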