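Package: glycoquant
Title: Label-Free Quantification of Site-Specific Protein Glycosylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates glycopeptide identifications from Byonic-style search
    exports with MS1 precursor peak areas from Proteome-Discoverer-style
    exports to quantify site- or peptide-specific glycosylation. Parses glycan
    monosaccharide compositions, computes theoretical monoisotopic glycan
    masses, assigns the glycosylated residue within each peptide by delta-mass
    matching, removes decoy and contaminant identifications, deduplicates
    peptide-spectrum matches to the highest-area precursor, and aggregates
    areas into glycoform proportions and site occupancies per sample. Includes
    a two-group comparison layer (unpaired t-tests on glycoform proportions)
    and a simulator that writes matched identification and area exports from a
    planted ground-truth glycoproteome for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
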