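Package: dblipidoid
Title: Combinatorial Design and Rule-Based Screening of Degradable
    Branched Ionizable Lipidoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Virtual synthesis and screening toolkit for degradable
    branched (DB) ionizable lipidoids built by a one-pot, two-step,
    three-component reaction: epoxide ring-opening on an amine headgroup
    followed by acylation of the resulting hydroxyls with acyl chlorides.
    Provides building-block registries, reaction-transform enumeration of
    lipidoid libraries with molecular formula and mass bookkeeping,
    ester-hydrolysis (metabolite) accounting, structural descriptors
    (total tail carbons, tail symmetry, headgroup class, metabolite
    mass), a rule-based potency classifier and ranker, a conformer-based
    lipid packing-parameter estimate, a synthetic two-channel screening
    data generator, and structure-activity analysis utilities
    (heat maps, contour statistics, correlation and threshold-necessity
    tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    ChemmineR,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
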