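Package: switchnet
Title: Switch-Gene Detection in Co-Expression Networks by Heat Cartography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies "switch genes" in case/control gene-expression data
    by building a thresholded Pearson co-expression network, partitioning it
    into communities with seeded k-means on expression profiles, and placing
    every node on the heat-cartography plane defined by the within-module
    degree z-score (Zg) and the clusterphobic coefficient (Kpi), coloured by
    the average Pearson correlation with network neighbours (APCC). Switch
    genes are the fight-club hubs (APCC < 0) that are not local hubs
    (Zg < 2.5) and link mostly outside their community (Kpi > 0.8). Includes
    a differential-expression filter with Benjamini-Hochberg correction,
    targeted node-removal robustness curves, hypergeometric
    over-representation analysis against GMT gene-set collections, topology
    ranking of transcription-factor/miRNA/chemical regulators, multi-list
    overlap tables, and a synthetic-data generator with planted modules,
    differential expression and switch genes for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
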