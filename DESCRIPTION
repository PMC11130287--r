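Package: memtopo
Title: Intramembrane Positioning Analytics for Hairpin Membrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative machinery for determining how monotopic hairpin
    proteins sit in bilayer versus lipid-droplet monolayer membranes.
    Implements cysteine-accessibility (PEGylation) topology mapping from
    gel-band intensity tables, continuous-wave EPR power-saturation curve
    fitting with membrane depth parameter (Phi) analysis, structure-based
    membrane-geometry observables (insertion depth, helix tilt, hairpin
    opening angle), and a self-consistent WHAM estimator of umbrella-sampling
    free-energy profiles with bootstrap errors. A synthetic-data module
    generates every input with known ground truth so the full pipeline can be
    validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    stats,
    tools,
    minpack.lm,
    bio3d,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
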