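Package: supercoilr
Title: Coarse-Grained Simulation of Transcription-Induced Supercoiling in
    Chromatin Fibres
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Twistable bead-spring polymer models of 10 nm chromatin fibres
    (400 bp per bead) with RNA-polymerase-like torsional motors,
    topoisomerase-I-like swivels, topoisomerase-II-like passage zones and
    rigid cohesin rings. Provides a Langevin dynamics engine with a
    side-site material frame, topological observables (writhe, twist,
    linking number, persistence length, intersegmental-passage detection),
    Hi-C-style contact maps with domain and boundary scoring, and a
    declarative scenario runner that reproduces divergent-transcription
    domain formation in fission yeast chromosome fragments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
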