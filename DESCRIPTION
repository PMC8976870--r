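Package: htmagent
Title: Hierarchical Temporal Memory Agents with Intrinsic Motivation and Dreaming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Building blocks and experiment harness for a biologically inspired
    reinforcement-learning agent operating on sparse distributed representations
    (SDRs). Provides a spatial pooler (k-winners Hebbian encoder), a simplified
    temporal memory for online sequence learning with per-step anomaly and
    confidence signals, online pattern clustering, a basal ganglia-thalamus
    action-selection circuit with dual (intrinsic/extrinsic) TD-dopamine
    pathways, an entropy-based empowerment estimator over the learned transition
    memory, an anomaly-gated model-based planner that learns in imagination
    ("dreaming"), a two-level sensorimotor hierarchy that forms abstract
    options, deterministic grid-world environments with multi-channel binary
    windowed observations, and protocols to compare agent variants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
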