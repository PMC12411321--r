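Package: fieldpam
Title: Processing and Interpretation of Long-Term Field Monitoring-PAM
    Chlorophyll Fluorescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for long-term, unattended pulse-amplitude-modulated (PAM)
    chlorophyll fluorescence monitoring in the field. Reads delimited
    monitoring-fluorometer records (timestamp, PAR, temperature, F' and Fm'),
    removes the temperature dependence of the measuring-light output,
    classifies records into day and night, flags weather and instrument
    artifacts (dew, rain, snow, drift, low signal) with recovery-based
    unflagging, estimates seasonal reference fluorescence levels (FmR, F0R)
    by regression of nightly Fm on Fv/Fm, and computes the full diurnal and
    seasonal set of photochemical (PQ, qL) and non-photochemical (NPQ)
    quenching parameters and quantum yields. Includes a lake-model forward
    simulator of a boreal evergreen season with injected artifacts and
    per-record ground truth, so every processing stage can be exercised and
    scored without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
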