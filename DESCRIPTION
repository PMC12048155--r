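Package: structvep
Title: Structure-Informed Zero-Shot Protein Variant Effect Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes proteins jointly from sequence and backbone structure
    with a roto-translation equivariant graph neural network, pre-trained by
    a residue-denoising objective, and scores amino-acid substitutions
    zero-shot by a per-site log-odds fitness ratio. Includes kNN residue
    graph construction with geometric edge features from PDB backbones,
    residue perturbation strategies (multinomial replacement, BERT-style
    masking, Gaussian embedding noise, embedding recoding), a from-scratch
    trainable equivariant message-passing core with hand-derived gradients,
    deep mutational scanning assay curation for thermostability benchmarks,
    Spearman rank-correlation evaluation with bootstrap summaries, and a
    synthetic fixture generator (idealized helical backbones and
    planted-signal assays) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
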