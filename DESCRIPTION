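Package: intronHet
Title: Detection and Analysis of Intronic Heterochromatin from Bisulfite
    Sequencing Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the study of heterochromatic introns in plant genomes.
    Implements per-cytosine methylcytosine calling from bisulfite cytosine
    reports (binomial test against the bisulfite non-conversion rate with
    Benjamini-Hochberg correction), CHG-methylation heterochromatic domain
    detection (runs of at least five consecutive methylated CHG sites with
    mean level at least 0.5), classification of introns and genes by
    intronic heterochromatin, transposable-element location and methylation
    taxonomy, positional permutation and Fisher enrichment statistics,
    ROKU-style expression-specificity entropy, a pre/post-intron read-ratio
    test for premature transcription termination between genotypes, and
    Nei-Gojobori Ka/Ks and intron p-distance estimation for ortholog pairs.
    A fully deterministic synthetic-data generator with recorded ground
    truth supports end-to-end testing without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
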