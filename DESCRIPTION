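Package: wgtfate
Title: Gene-Family Evolution After Whole-Genome Triplication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for studying the evolution of a gene family after a
    polyploidy event, modelled on the Brassica rapa whole-genome
    triplication (WGT) and its ABC-transporter complement. Provides
    Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor correction,
    selection-pressure classification and synonymous-clock duplication
    dating; gene-catalog summaries, domain-topology classification and
    tandem-array detection; subgenome retention/fractionation analysis
    with two-proportion tests; IUPAC degenerate cis-element scanning of
    promoter sequences; expression-based duplicate-gene fate
    classification (conservation/sub-functionalization,
    neo-functionalization, pseudogenization) and comparative-Ct qPCR
    quantification; and seeded synthetic-data generators with planted
    ground truth so that every stage is testable without external
    downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
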