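Package: ecoseed
Title: Reverse Ecology of Microbial Communities from Metabolic Network Topology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs directed compound graphs from KEGG-style reaction
    annotations, predicts each organism's seed set (the compounds it must
    acquire exogenously) from the source strongly connected components of its
    metabolic network, and quantifies pairwise competition and
    complementarity between community members as confidence-weighted seed-set
    overlap indices with permutation p-values. Includes Jaccard co-occurrence
    from species-by-sample abundance tables and a Mantel permutation test for
    comparing predicted interactions with observed co-occurrence, plus
    synthetic community generators for offline validation and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
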