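Package: metaprof
Title: Molecular-Profile Prioritization of Gut Microbial Metabolites for Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks chemicals and gut microbial metabolites by how closely
    their pathway-level molecular profiles match a disease's profile.
    Profiles are built by resampling-based gene-set enrichment (observed
    pathway overlap of an entity's associated genes scored against random
    same-size gene sets), chemicals are ranked by overlap, Jaccard or
    cosine similarity of profile feature sets, rankings are evaluated
    against known positives by recall, mean/median percentile and decile
    enrichment, and top hits are characterized through harmonic combined
    ranking of pathways and mouse mutational phenotypes shared with the
    disease. Includes a synthetic-universe generator with planted
    disease-associated chemicals so the whole pipeline is testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
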