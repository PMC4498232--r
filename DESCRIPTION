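Package: dnasga
Title: DNA Sequence Identification with Single-Error-Correcting BCH Codes
    over Galois Rings and Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decides whether a DNA coding sequence, under a nucleotide
    labeling, is a codeword of a single-error-correcting BCH code over
    GF(4^m) or the Galois ring GR(4,m), and, when the sequence lies at
    Hamming distance one from a codeword, emits the code-generated
    sequence, the altered position and the codon/amino-acid consequence
    under canonical and deviant genetic codes.  Includes exact arithmetic
    in GF(4), GF(4^m), Z4[x] and GR(4,m), the Graeffe/Hensel lift of
    binary primitive polynomials, syndrome single-error decoders for both
    algebras, a brute-force identification oracle, a registry of built-in
    code presets, nucleotide labelings, genetic-code tables with
    mitochondrial and nuclear codon reassignments, FASTA input, TSV/JSON
    reports, and a seeded synthetic fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
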