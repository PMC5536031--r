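Package: hotspotRP
Title: Random-Projection Ensemble Prediction of Protein Hotspot Residues
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts protein-protein interaction hotspot residues from whole
    protein sequences. Each residue is encoded by the standard deviations of
    the elementwise products between its sequence profile (PSSM frequencies)
    and AAindex1 physicochemical amino-acid indices, concatenated over a
    sliding window. Encoded instances are reduced by column-normalised random
    projections and classified by an ensemble of instance-based (k-nearest
    neighbour) learners trained on class-rebalanced data, ranked by validation
    F1 and combined by majority vote. Includes readers for the AAindex1
    flat-file, PSI-BLAST ASCII PSSM and FASTA formats, a seeded synthetic
    corpus generator with a plantable hotspot signal, evaluation metrics
    (sensitivity, precision, F1, MCC) with a random-predictor baseline, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    class,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
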