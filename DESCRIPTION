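Package: mutopia
Title: Joint Inference of Mutational Spectra and Genome-Wide Mutation-Rate
    Topography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A generative probabilistic model of somatic mutagenesis that
    jointly infers mutational-process spectra and their genome-wide
    mutation-rate topographies as nonlinear functions of genomic features.
    Mutations are modelled as draws from a mixture of latent processes; each
    process carries a macro-scale log-rate function fitted by gradient-boosted
    trees, a baseline 192-channel stranded trinucleotide spectrum, and sparse
    feature-driven spectrum adjustments. Includes feature-defined genome
    binning, copy-number-aware mutation ingestion with clustered-mutation
    down-weighting, mean-field variational inference with optional stochastic
    bin subsampling, pseudo-R2 evaluation and model ablations, NNLS
    validation, exposure refitting for new samples, a cohort simulator with
    recovery benchmarks, topotype clustering of transferred rate profiles,
    and Shapley feature attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    IRanges,
    S4Vectors,
    xgboost,
    glmnet,
    igraph,
    pracma,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
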