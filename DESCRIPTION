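Package: speckleflow
Title: Pulse-Waveform Analysis of Laser Speckle Flowgraphy Perfusion Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing optic-nerve-head perfusion recordings from
    laser speckle flowgraphy (LSFG). Detects cardiac cycles in mean-blur-rate
    (MBR) time series, builds the phase-normalized composite pulse cycle, and
    computes the eight standard pulse-waveform indices (blowout time, blowout
    score, skew, acceleration time index, rising and falling rate, flow
    acceleration index, resistivity index) together with regional mean MBR
    (MA/MV/MT) from composite flow maps with automatic vessel extraction.
    Includes the reliability and association statistics used in test-retest
    LSFG studies (coefficient of variation, ANOVA-based intraclass
    correlation, Pearson/linear regression with confidence bands, paired and
    independent comparisons, success-rate chi-square, and derived ocular
    hemodynamics), plus a synthetic cohort generator that emulates the data
    structure of a repeated-scan LSFG study for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
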