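Package: radscav
Title: Radical-Scavenging Kinetics of Antioxidants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing toolkit for ranking antioxidants by their
    radical-scavenging kinetics from quantum-chemical thermochemistry.
    Implements thermodynamic screening of hydrogen-atom-transfer (HAT),
    radical-adduct-formation (RAF), SPLET and SET-PT pathways, conventional
    transition-state-theory rate constants with Eckart (ZCT-0) tunneling
    corrections, Marcus-theory electron-transfer rates with diffusion
    correction, Smoluchowski diffusion-limited rates, acid-base speciation,
    relaxed-scan classification with spin-crossing detection, and aggregation
    into overall rate constants, branching ratios and Trolox-relative
    antioxidative capacities. Includes a synthetic mechanism-network generator
    for end-to-end testing without electronic-structure calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
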