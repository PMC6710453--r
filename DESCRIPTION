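Package: msarousal
Title: Psychophysiological Arousal Analysis for Mortality-Salience Protocols
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis of multi-channel psychophysiological
    recordings from a two-condition (mortality salience vs dental pain
    salience) between-subjects protocol. Derives nine arousal indicators
    (heart rate, HF/LF heart-rate-variability band power, pre-ejection
    period, cardiac output, mean arterial pressure, total peripheral
    resistance, respiration rate, and the nonspecific electrodermal
    fluctuation rate) from raw ECG, impedance-cardiographic, respiration
    and electrodermal signals; segments them onto the experimental
    timeline; multiply imputes missing cells by predictive mean matching
    with Rubin pooling; and evaluates segment-versus-baseline and
    between-condition contrasts with FDR-corrected t tests and JZS
    (Cauchy-prior) Bayes factors. Includes a synthetic-recording
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
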