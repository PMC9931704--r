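Package: capkd
Title: Pediatric Pharmacokinetics of Captopril in Chronic Kidney Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting captopril disposition in children with
    chronic kidney disease (CKD). Scales an adult clearance model to
    pediatric subjects by allometry, links renal clearance to glomerular
    filtration rate, overlays CKD pathophysiology (reduced non-renal
    clearance, altered protein binding, hematocrit and gastric emptying),
    simulates oral concentration-time profiles to single dose or steady
    state with a reduced two-compartment model, extracts pharmacokinetic
    parameters by non-compartmental analysis (Cmax, Tmax, AUC, CL/F), and
    scores predictions against observations with fold-error, average-fold-
    error, confidence-interval and prediction-interval-coverage metrics.
    Ships the reference pediatric demographic and pharmacokinetic tables
    as plain-text fixtures together with a seeded synthetic-study
    generator for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
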