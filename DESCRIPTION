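Package: breathturn
Title: Speech-Breathing Coordination Analysis for Conversational Turn-Taking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to link respiratory-cycle maxima to conversational speech
    onsets. Repairs sensor-saturation plateaus in respiration-belt recordings
    by spline interpolation, resamples and aligns traces to a scanning-session
    clock, detects inspiration-to-expiration maxima, segments speech into
    inter-pausal units (IPUs) by RMS thresholding with a 200 ms pause rule,
    classifies each respiration maximum as speech-associated (Resp+) or not
    (Resp-), and characterises the lag between breath maxima and speech onsets
    (MAD outlier rejection, Lilliefors normality, skewness, density-mode
    estimation, group comparison). Includes a synthetic-data generator with
    known ground truth (asymmetric breath cycles, speech-locked inhalation
    peaks, amplitude-rail saturation, turn-taking IPU sequences, curvilinear
    dark sulcus paths on bright images) and an intensity-following tracer that
    draws the central sulcus on an axial slice and categorises an activation
    peak relative to it.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    yaml,
    nortest,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
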