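Package: pared
Title: Degradome (PARE-Seq) Validation of miRNA and Secondary siRNA Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for degradome / PARE (parallel analysis of
    RNA ends) sequencing in plants: adapter trimming and contaminant
    filtering of degradome reads, exhaustive all-placement alignment to a
    transcriptome within a mismatch budget, per-transcript cleavage profiles
    with CleaveLand-style category classification (categories 0 and 1
    merged), Allen-score and minimum-free-energy-ratio duplex scoring of
    small RNA target sites, a stringent filter stack with multi-target
    retention so that paralogous family members sharing a cut-site sequence
    are all reported, cross-sample target comparison, and detection plus
    cascade validation of 21-nt phased secondary siRNAs (tasiRNAs and
    phasiRNAs) with a hypergeometric phase-register statistic. Includes a
    fully seeded synthetic-data generator that plants target sites,
    degradome peaks and phased siRNA ladders with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
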