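Package: lifeREC
Title: Lifespan Disparity Decomposition and the Ratio of Expansion to
    Compression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring lifespan disparity from age-specific
    mortality schedules. Builds continuous-approximation life tables on a
    fine age grid, computes life years lost due to death (e-dagger), the
    threshold age separating mortality compression from expansion, and the
    decomposition of disparity into compression and expansion components,
    summarised by their ratio (REC) and difference (DEC). Includes the
    decomposition of change in disparity over time via age-specific rates
    of mortality decline and the associated sensitivity function, a
    Siler-model simulator of long-run mortality decline scenarios,
    closed-form hazard fixtures for validation, readers for Human
    Mortality Database style text files, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, pracma
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
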