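Package: pol3kit
Title: Design and Evaluation of RNA Polymerase III Promoters for CRISPR
    Guide Expression in Monocots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for deriving novel RNA polymerase III (Pol III)
    promoters from a training set of monocot U6/U3 snRNA promoters and for
    evaluating the CRISPR/Cas12a editing outcomes they enable. Implements
    position-binned k-mer motif overrepresentation discovery, a composite
    promoter-likeness scoring model (position-specific 6-mer frequency and
    enrichment plus dinucleotide entropy), simulated-annealing sequence
    design with motif seeding and post-hoc trimming, TATA/USE/MSP promoter
    grammar annotation with spacing rules, LbCas12a crRNA cassette and
    construct assembly, amplicon-sequencing indel quantification with
    deletion profiles and population summaries, and seeded synthetic data
    generators for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
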