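Package: hrvei
Title: Heart Rate Variability Markers of Emotional Intelligence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline linking heart rate variability (HRV) to
    emotion-recognition performance. Detects R peaks in ECG, derives cleaned
    RR-interval series segmented into baseline and stimulus epochs, computes a
    21-index HRV set (time domain, frequency domain, respiratory sinus
    arrhythmia) over sliding windows, summarises each index series with the
    affect-dynamics triad (variability, instability, inertia) after baseline
    normalization, scores emotion-recognition questionnaires on a 1200-point
    scheme, and locates the evaluation-score cut-point that maximizes the
    number of HRV features discriminating low from high scorers. A synthetic
    data module generates RR series, ECG records, cohorts and questionnaire
    responses with known ground truth so the whole pipeline is testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
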