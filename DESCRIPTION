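Package: devkin
Title: Comparative Analysis of Developmental Gene Expression Kinetics
Version: 0.1.0
Authors@R: person("devkin", "developers", role = c("aut", "cre"),
    email = "devkin-devel@example.org")
Description: Tools for comparing developmental gene-expression time courses
    between species. Fits four-parameter sigmoidal activation curves to
    per-gene kinetics and extracts initiation (half-rise) times, estimates
    the linear developmental-time scaling between two species from
    orthologue initiation times, clusters temporal profiles with k-means
    and classifies orthologues as conserved or diverged by centroid
    distance, and quantifies stage-by-stage interspecies conservation
    (hourglass versus funnel patterns) with correlation matrices, variance
    profiles and PCA sample grouping. Includes a two-species synthetic
    data generator with full ground truth and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
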