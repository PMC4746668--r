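Package: famsurvey
Title: Gene-Family Survey Toolkit for Plant Transcription Factors
Version: 0.3.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of the classic
    gene-family survey workflow used to characterize plant transcription
    factor families such as the cotton TCP family: profile-HMM domain
    scanning with empirical P-value calibration, PROSITE confirmation,
    redundancy curation, progressive multiple alignment and neighbor-joining
    phylogeny with bootstrap support, paralog detection by the 70/70
    coverage-similarity criterion, Nei-Gojobori Ka/Ks estimation with
    molecular-clock dating (T = Ks/2*lambda), exon/intron architecture
    extraction, ZOOPS expectation-maximization motif discovery, and qPCR
    delta-Ct relative-expression profiling. A seeded synthetic-data
    generator emulates every input (proteome, CDS, gene models, Ct tables)
    with recorded ground truth so each stage closes its own testing loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
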