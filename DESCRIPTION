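Package: isobolab
Title: Fixed-Ratio Isobolographic Analysis of Antinociceptive Drug Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of drug-combination antinociception in the
    rat formalin test: reduction of flinch-count time courses to trapezoidal
    AUCs and percent antinociception by phase, effective-dose (ED30/ED50)
    estimation by inverse prediction from linear effect-vs-log10(dose) fits
    with delta-method standard errors, fixed-ratio isobolographic analysis
    under Loewe additivity (theoretical vs experimental ED comparison by
    Student's t-test), and the interaction index with synergy classification.
    Includes a synthetic formalin-test study generator with known ground
    truth (biphasic vehicle intensity, log-linear dose-effect margins, a
    tunable Loewe synergy factor, Poisson observation noise) so the whole
    pipeline can be exercised and calibrated without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
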