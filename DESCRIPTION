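Package: codonassoc
Title: Quantitative Association Between Codon Positions and Amino Acid
    Physicochemical Properties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exhaustively enumerates nucleotide grouping and value-assignment
    schemes at each codon position, correlates the resulting per-amino-acid
    position values with bundled physicochemical property scales (Kyte-Doolittle
    hydropathy, Grantham polarity and composition, polar requirement, and
    others), and extends the strongest association to the gene level through
    the T2-A2 second-position frequency statistic and protein GRAVY scores.
    Includes group comparisons of informational versus operational genes
    (COG/KOG functional categories) by t-test and chi-square, a synthetic
    coding-sequence simulator with controllable second-position composition
    bias, and tab-separated report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
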