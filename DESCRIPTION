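Package: coevoqtl
Title: Co-Conservation and Coevolution Analysis of SNP-Gene Regulatory Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the shared evolutionary history of
    regulatory SNP-gene (eQTL) pairs. Builds per-base conservation
    profiles around loci, reduces them by logarithmic binning and
    clusters them into high/low-conservation classes; extracts
    species-by-species similarity matrices from whole-genome multiple
    sequence alignments and scores coevolution of locus pairs by sparse
    correlation of those matrices (a bipartite mirrortree approach
    robust to shared missing alignments); and uses coevolution scores to
    prioritize cis-eQTL association tests under Benjamini-Hochberg
    multiple-testing correction, including the beta/gamma enrichment
    identity and distance-matched and downsampling controls. Includes a
    fully seeded synthetic-data generator (species-tree sequence
    evolution with planted coevolved pairs, conservation tracks, eQTL
    p-value catalogs) with ground-truth manifests for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    phangorn,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
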