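Package: mitocompare
Title: Comparative Analysis of Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative mitogenomics of insects: reading and writing
    annotated circular mitochondrial genomes (GenBank flat file, FASTA plus a
    feature table), auditing gene content, start/stop codons, gene overlaps and
    spacers around the circle, and gene-order rearrangements; nucleotide
    composition, AT/GC strand skews and relative synonymous codon usage (RSCU)
    under the invertebrate mitochondrial code; per-gene p-distances,
    Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction, and a
    distance-threshold conspecificity assessment for closely related
    mitogenome pairs; classification of tRNA cloverleaf stem pairs
    (Watson-Crick, G-U wobble, mismatch); and a seeded generator of realistic
    annotated mitogenomes and diverged sister genomes with ground-truth
    mutation logs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
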