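Package: niptkmer
Title: Alignment-Free Detection of Fetal Aneuploidies from Cell-Free DNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Non-invasive prenatal testing (NIPT) of fetal trisomies without read
    mapping. Builds filtered per-chromosome lists of unique 25-mers from a
    reference genome (removing non-unique, polymorphic, low-complexity and
    population-unstable k-mers via a Poisson coverage filter), counts those
    k-mers directly in raw FASTQ reads of cell-free DNA samples, and calls
    trisomies and fetal sex with a per-chromosome linear-regression coverage
    model, z-scoring against a euploid reference cohort, and Mahalanobis
    distance quality control. Includes a seeded synthetic-data generator for
    toy genomes, diploid individuals, and maternal/fetal cfDNA read mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    optparse,
    Biostrings,
    GenomicRanges,
    vcfR,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
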