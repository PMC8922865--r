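Package: kneecut
Title: Cutoff Point Identification in Ranked Descriptive Omics Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies the cutoff point separating the low-value background
    from the small dominant set in descriptive high-throughput biological
    data (gene expression, protein abundance, chemical-sensitivity scores).
    Values are ranked ascending, a chord is drawn from the first to the last
    point of the ranked curve, and the rank maximizing the perpendicular
    distance to the chord is taken as the cutoff between the slowly growing
    low-value phase and the rapidly growing high-value phase. Includes a
    truncation-robustness sweep that emulates low-abundance detection
    dropout, a seeded generator of biphasic synthetic profiles with known
    knee, TSV/CSV readers and writers, diagnostic plots, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
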