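Package: rxprep
Title: Transparent Preparation of Prescription Records into Time-Varying
    Drug Exposure Episodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts raw primary-care prescription records (quantity, numeric
    daily dose, treatment days, derived duration) into time-varying binary
    drug-exposure episodes through an explicit ten-node, 54-option decision
    framework covering value cleaning, stop-date derivation, same-day
    duplicates, overlapping prescriptions and gap closure. Every complete set
    of choices (a "pathway") is a reproducible data-preparation recipe; the
    package enumerates, samples and executes pathways, audits per-node record
    counts, fits time-varying Cox proportional-hazards contrasts on the
    resulting exposure timelines, and runs two-stage sensitivity experiments
    (random pathways plus one-at-a-time perturbations of a primary pathway)
    that quantify how preparation assumptions move hazard-ratio estimates.
    Includes a synthetic cohort generator with known ground-truth exposure and
    outcome hazards so the full pipeline is testable without access to any
    real electronic health record extract.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
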