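Package: specbind
Title: Multi-Spectroscopic Analysis of Protein-Ligand Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing small-molecule binding to serum
    albumins and other fluorescent proteins from steady-state spectroscopy.
    Implements Stern-Volmer and modified Stern-Volmer quenching fits with
    biphasic-window detection, double-logarithmic (Hill) binding-constant
    fits, van't Hoff thermodynamics with interaction-force classification,
    Forster resonance energy transfer (FRET) distance estimation from
    spectral overlap, inner-filter correction, synchronous-fluorescence and
    second-derivative absorbance probes, circular-dichroism alpha-helix
    quantification, and site-marker displacement comparison. Includes a
    synthetic-data generator with known ground truth for end-to-end testing,
    broom-style tidiers and ggplot2 autoplot methods for every result type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
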