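Package: bgcscaffold
Title: Biosynthetic Gene Cluster Mining and Secondary-Metabolite Scaffold Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects polyketide synthase (PKS) and nonribosomal peptide
    synthetase (NRPS) biosynthetic gene clusters in genomic input, parses
    their domain architecture into modules and blocks, predicts substrate
    specificity of acyltransferase and adenylation domains with random
    forests trained on one-hot encoded alignments, assembles putative
    secondary-metabolite scaffolds from per-module building blocks, predicts
    postsynthetic modifications from domain counts, and ranks the scaffolds
    against natural-compound libraries with a combined fingerprint,
    multi-fragment maximum-common-substructure and Bray-Curtis score.
    Profile hidden Markov models are built and scanned through HMMER,
    alignments through MAFFT, and molecule handling through OpenBabel.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    igraph,
    pROC
SystemRequirements: HMMER3 (hmmbuild, hmmsearch), MAFFT, optionally prodigal
Config/testthat/edition: 3
RoxygenNote: 7.3.3
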