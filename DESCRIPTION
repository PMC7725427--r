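Package: headscreen
Title: Dichotic Headphone Screening Tests and Their Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for screening remote participants' audio equipment in
    online auditory experiments. Implements three dichotic screening tests
    -- a Huggins Pitch detection test, the anti-phase tone loudness test,
    and a binaural beat test -- including stimulus synthesis at 44.1 kHz,
    three-alternative forced-choice trial pools, block sampling and
    scoring, and pass/fail rules. Provides a signal-detection evaluation
    framework (ROC curves over pass thresholds, AUC, d-prime, bootstrap
    and permutation inference on AUC differences), estimation of the
    proportion of headphone users in an unscreened cohort by least-squares
    mixture fitting of reference score distributions, and a virtual
    listener simulator with explicit playback-mixing models for end-to-end
    validation without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
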