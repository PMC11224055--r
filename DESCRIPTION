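Package: pegdel
Title: Design and Analysis of Prime-Editing Programmed Genomic Deletions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for programming precise genomic deletions (50-2000 bp)
    with prime editors in plants. Designs single pegRNA + nicking-sgRNA (PE3)
    and dual-pegRNA (PDel) configurations, synonymously recodes RT-template
    "patch" regions (PDel/Syn) to remove template/target homology, assembles
    annotated epegRNA expression cassettes, designs junction-specific and
    flanking detection primers, and classifies amplicon deep-sequencing reads
    per plant into precise-deletion / indel / wild-type outcomes with
    homozygous / heterozygous / chimeric zygosity calls and cohort-level
    editing statistics. A cohort simulator generates FASTQ reads with known
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
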