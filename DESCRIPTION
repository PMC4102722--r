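Package: mosatwin
Title: Somatic Mosaicism Detection in Monozygotic Twin Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting somatic single-nucleotide and copy-number
    differences between matched samples of monozygotic twins. Implements a
    phred-scaled genotype-difference (somatic) score from diploid genotype
    likelihoods, Fisher's exact allele-count discordance testing with and
    without read-quality filters, candidate-site selection for four-sample
    twin designs, indel-misalignment-aware arbitration of candidate calls,
    a windowed depth-ratio CNV caller with a twin-differential filtering
    cascade (reciprocal overlap, healthy-twin exclusion, mappability and
    loss-of-heterozygosity support), and a carriership-based disease-risk
    score (summed log odds ratios) ranked against a control cohort. A
    synthetic twin-pair data generator with planted ground truth supports
    end-to-end validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
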