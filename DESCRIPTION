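Package: abetapkpd
Title: Semimechanistic PK/PD Modeling of Beta-Amyloid Lowering Compounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Indirect-response (turnover) pharmacokinetic/pharmacodynamic
    modeling of beta-amyloid (Abeta) lowering by secretase inhibitors and
    modulators. Simulates vehicle-normalized Abeta time courses in brain and
    CSF under a drug concentration drive, estimates turnover (kout) and
    drug-effect parameters (Imax, IC50, gamma) from destructive-sampling
    animal studies by nonlinear least squares, derives the intrinsic
    exposure-response (Rgen) relationship, scales Abeta clearance kinetics
    across species by allometry, and generates synthetic preclinical studies
    with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
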