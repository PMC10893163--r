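Package: vbesim
Title: Virtual Bioequivalence Trial Simulation for Modified-Release Oral Formulations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for in silico (virtual) bioequivalence assessment of
    modified-release oral drug products. Implements the f2 dissolution-profile
    similarity factor, Weibull release-model fitting by bounded nonlinear least
    squares, a reduced release-rate-limited oral pharmacokinetic simulator
    (Weibull release into a first-order absorption and one-compartment
    well-stirred-liver disposition model, with multi-dose regimens, titration
    schedules and static competitive CYP inhibition), log-normal virtual
    population generation, noncompartmental endpoint estimation (Cmax, AUC,
    terminal slope), parallel-design virtual bioequivalence trials decided by
    the 90% confidence interval of the test/reference geometric mean ratio
    against 80-125% limits, and a central-limit-theorem based study-power
    procedure with power-versus-sample-size sweeps. A seeded synthetic-data
    generator produces replicate dissolution data sets and runnable end-to-end
    trial scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
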