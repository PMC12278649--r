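Package: pairviews
Title: Multi-Modal View Augmentation for Drug-Pair Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts drug-combination outcomes (cell-line synergy, xenograft
    tumor-volume response, typed drug-drug interactions) by expanding every
    drug pair into up to 64 modality-pair views.  Eight modality-specific
    encoders (SMILES transformer, molecular-graph message passing, target
    gene sets expanded on a protein-protein interaction network, 3D-aligned
    and text embeddings, random-walk-with-restart ontology embeddings,
    side-effect and sensitivity profiles) project heterogeneous drug payloads
    into a shared space; an augmentor combines them pairwise with context
    features, and a top-k noisy-label aggregator refines the per-view
    predictions into a single score.  Training combines a supervised
    objective with InfoNCE and soft-label consistency terms on a built-in
    reverse-mode automatic-differentiation tape.  Includes downstream
    discovery procedures (synthetic-dosage-lethality pathway mining, patient
    pathway-activation labels, Fisher's-exact drug-class interaction
    networks), data-split protocols with leakage guarantees, evaluation
    metrics, and deterministic synthetic-fixture generators for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
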