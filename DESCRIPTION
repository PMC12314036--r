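Package: triggernet
Title: Signed-Network Propagation Models for Drug Off-Target Adverse-Event Mechanisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ensemble propagation models over signed, directed protein-interaction
    networks for linking drug target and off-target profiles to adverse-event
    mechanisms. Provides a perceptron-like signal propagation model trained by
    simulated annealing against stimulus-response truth tables, distance-weighted
    triggering scores with a classification rule for off-targets that induce
    pathophysiological processes, mechanism-of-action pathway extraction with
    Graphviz export, tSignal-based cotreatment-interference statistics
    (Wilcoxon rank-sum with Benjamini-Hochberg correction), and a synthetic
    benchmark generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
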