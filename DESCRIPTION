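Package: shellprefs
Title: Preference-Function Analysis of Repeated Shelter-Choice Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates individual preference functions from repeated
    discrete choices among an ordered array of manipulated stimulus levels,
    as used in shelter- and nest-site choice experiments with shell-dwelling
    cichlid fish. Fits penalized cubic spline preference curves to per-fish
    choice counts, extracts the preference-function traits peak, strength
    and tolerance, builds Monte-Carlo null distributions of those traits
    under purely random choice, and compares choice-task groups against the
    random-choice reference with heteroscedastic linear models and
    single-step Dunnett-type and all-pairs contrasts. Includes a binomial
    logistic model for binary (chirality) choice tasks and a synthetic-data
    generator that emulates wild shell morphometrics, latent preferences
    and trial structure so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    mgcv,
    nlme,
    stats,
    jsonlite,
    yaml,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    car
Config/testthat/edition: 3
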