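Package: sipenrich
Title: Quantitative DNA Stable Isotope Probing Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for DNA stable isotope probing (SIP)
    experiments on CsCl buoyant-density gradients. Converts refractive
    index to buoyant density, normalizes per-fraction 16S rRNA gene qPCR
    quantities to ratios of quantities, computes per-taxon relative gene
    copy numbers inside a heavy-density window and the percentage
    enrichment of a 13C-labeled gradient over its 12C control, with a
    confidence-interval noise threshold. Also provides peptide elemental
    composition and isotope-labeling accounting with nominal SIM m/z,
    zero-order substrate decay kinetics, a peptide nitrogen mass balance
    (hydrolysis, remineralization, biomass incorporation, residual DON)
    and bacterial phosphorus demand, plus a seeded synthetic-data
    generator that emulates paired labeled/unlabeled gradients and
    incubation time series for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
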