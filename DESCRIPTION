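Package: readspec
Title: Machine-Readable Specifications of Sequencing Read Structure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Defines a machine-readable, YAML-serialized specification of the
    structure of sequenced reads from genomics assays. A library molecule is
    modeled as an ordered tree of annotated Regions (barcodes, UMIs, cDNA,
    adapters, primers, ...) glued 5' to 3'; meta Regions group child Regions
    and a read corresponds to a meta Region. The package validates documents
    against the schema, queries and positionally indexes Regions (0-based,
    half-open intervals), renders human-readable diagrams, splits FASTQ
    records at Region boundaries, emits technology strings for single-cell
    preprocessing tools (kallisto bustools, STARsolo, simpleaf), and
    generates fully synthetic specs, barcode onlists and reads with known
    ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    yaml,
    tools,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
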