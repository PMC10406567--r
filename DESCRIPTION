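Package: hrvt
Title: Heart-Rate-Variability Thresholds from DFA Alpha-1 During Ramp Exercise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates heart-rate-variability thresholds (HRVT1, HRVT2) from
    RR-interval recordings of cycling ramp incremental tests using the
    short-term scaling exponent of detrended fluctuation analysis (DFA alpha-1).
    Provides RR-interval artifact detection and correction, smoothness-priors
    detrending, time-varying DFA over rolling two-minute windows,
    breath-by-breath gas-exchange preprocessing, mapping of threshold crossings
    to oxygen uptake and heart rate, cohort-level method-agreement statistics
    (Pearson correlation with standard error of estimate, Bland-Altman limits
    of agreement, ICC(3,1), repeated-measures ANOVA, paired t-tests), and a
    synthetic-participant generator with known ground-truth thresholds for
    validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
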