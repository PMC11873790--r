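Package: msparquet
Title: Columnar Storage and Fast Filtered Access for Ion-Mobility
    Mass-Spectrometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts data-independent-acquisition high-resolution mass
    spectrometry runs (low/high collision-energy alternation, optionally with an
    ion-mobility dimension) from mzML into a sparse long-format columnar schema
    stored in Apache Parquet, with sample metadata embedded both in the file's
    key-value metadata and in a JSON sidecar. Provides memory-frugal, row-group
    pruned queries over stored samples (total-ion, base-peak and extracted-ion
    chromatograms, spectrum slices, mobilograms, generic record filters), a
    linear drift-time calibration fitted from bin/drift-time pairs, and a
    deterministic synthetic HDMSE sample generator with ground truth so the
    whole pipeline can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    arrow,
    dplyr,
    jsonlite,
    methods,
    mzR,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
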