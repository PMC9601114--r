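Package: cubtools
Title: Codon Usage Bias Analysis for Protein-Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing codon usage bias in sets of protein-coding
    sequences: CDS validation and quality control, nucleotide composition by
    codon position, relative synonymous codon usage (RSCU) with the standard
    four-category classification, Wright's effective number of codons (ENC),
    parity-rule-2 and neutrality-plot diagnostics of mutation pressure versus
    natural selection, correspondence analysis of the gene-by-codon RSCU
    matrix, codon-pair context analysis with adjusted residuals, protein
    physicochemical properties (GRAVY, aromaticity, isoelectric point), and
    correlation of codon usage with externally supplied mRNA minimum free
    energies. Includes a synthetic CDS generator with controllable GC3,
    codon-bias strength and GC12-GC3 coupling so the whole pipeline is
    testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    vegan,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
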