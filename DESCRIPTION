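Package: verisim
Title: Simulation of Sequencing Reads with Verifiable Ground Truth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns empirical mutation models (trinucleotide-context
    substitution matrices, indel length distributions, regional rates) from
    variant calls and sequencing models (position-dependent Markov quality
    chains, sequencing-error statistics, GC coverage bias, fragment length
    distributions) from reads and alignments, then simulates single- or
    paired-end short reads from a reference genome at arbitrary ploidy.
    Every simulated dataset ships with "golden" truth files - a SAM of true
    alignments and a VCF of inserted variants with genotypes - plus
    comparison tools that score aligner and variant-caller output against
    that truth, including detection of equivalently represented variants
    and diagnosis of false negatives by coverage and mappability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    jsonlite,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
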