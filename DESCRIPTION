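Package: planktriage
Title: Human-in-the-Loop Triage for Metric-Space Zooplankton Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semiautomatic analysis of zooplankton monitoring samples from
    metric-learning image embeddings. Provides an exact cosine-similarity flat
    index over expert-verified 128-dimensional embeddings, a cascaded triage
    heuristic (detection-confidence gate, k-nearest-neighbour label proposal,
    density-cluster membership, one-class support-vector certainty) that routes
    each detected object either to automatic acceptance or to expert review, a
    simulated human-in-the-loop active-learning loop with retrieval-quality
    tracking (mAP@5), and a method-agreement suite for paired human versus
    machine abundance tables (sign-flip permutation test on the summed count
    difference, Wilcoxon signed-rank, Mann-Whitney, Pearson correlation,
    Bland-Altman analysis in log2 space, and category-level breakdowns).
    Seeded generators produce clustered unit-sphere embeddings, novel-class
    injections, drifting sample streams and biased paired count tables for
    end-to-end testing without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    e1071,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
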