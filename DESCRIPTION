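Package: fieldbar
Title: Barcoded Sample Identifiers and Standards-Compliant Contextual Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for consistent acquisition, validation, storage and
    standards-compliant export of sample contextual data (metadata) in
    environmental sequencing campaigns. Allocates unique three-part barcoded
    sample identifiers (Code 128 set C), generates and parses acquisition
    spreadsheets with parser-side validation against a registry of Genomic
    Standards Consortium (GSC) environmental and report packages, maintains a
    role-based multi-user sample repository with ownership and permission
    grants, and exports contextual data to KML, GCDML-style XML, MIxS-style
    sheets and INSDC structured comments paired with FASTA sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    Biostrings,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
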