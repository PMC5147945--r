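Package: conjuqc
Title: Quality Control of Fluorescent Antibody Conjugates by Bead-Based Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for flow-cytometric quality control of fluorescent antibody
    conjugates coupled to microspheres. Reads event-level list-mode data (FCS
    3.0/3.1 or a plain CSV dialect), gates the singlet bead population,
    classifies bead codes, computes geometric mean fluorescence intensity,
    CV and percent positive, calibrates intensities to molecules of
    equivalent soluble fluorochrome (MESF) from a five-population standard
    set, monitors instrument drift, and runs the decision layer for
    concentration optimization, coupling homogeneity, long-term stability
    (delta-FI, percent decrease) and fluorochrome-fading versus uncoupling
    verdicts. A synthetic-data module generates bead acquisitions with known
    ground truth so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
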