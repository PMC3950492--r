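Package: lipidmz
Title: Combinatorial Glycerophospholipid Enumeration, Mass Calculation, and
    m/z Search
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds the complete in-silico database of theoretically possible
    glycerophospholipid species across twelve LIPID MAPS subclasses (sixteen
    headgroup variants including the phosphoinositide PI/PIPx family),
    computes exact (monoisotopic) and average masses and adduct m/z values
    for the common single-charge MS ion modes, searches the database for
    species matching a query m/z under an absolute mass tolerance with
    class, chain-parity, and common-chain filters, and generates
    machine-readable structures (SMILES/SDF) for any species including all
    cis double-bond positional isomers under a configurable spacing rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ChemmineR
Config/testthat/edition: 3
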