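Package: alphatrimp
Title: Individualised Training-Impulse Methods from Heart Rate and
    Heart Rate Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying internal training exposure from
    beat-to-beat RR intervals and incremental exercise tests. Implements
    the blood-lactate-based individualised training impulse (iTRIMP) and
    an HRV-based alternative (alphaTRIMP) whose weighting factors are
    fitted exponentials of normalised short-scale detrended fluctuation
    analysis exponents (DFA-alpha1) against the fractional elevation of
    heart rate. Includes RR artifact detection and correction, windowed
    DFA-alpha1 computation, lactate-threshold and VO2max determination,
    principal-component-regression construct validation with k-fold
    cross-validation, and a synthetic-physiology generator for
    ground-truth recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
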