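Package: tnfit
Title: Competitive Fitness Estimation for Tn-Seq Carbon-Shift Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates per-gene competitive fitness from pooled transposon
    insertion sequencing (Tn-seq) count tables sampled before (t1) and after
    (t2) selective growth, using the log-ratio estimator in which a mutant
    lineage's expansion is compared with that of the rest of the population
    through the culture's optical-density expansion factor. Implements the
    exclusion filters used for conditional-essentiality screens (minimum t1
    representation, zero-count exclusion, baseline neutrality band,
    replicate-concordance) and the threshold cascade that classifies genes
    as differentially fit or substrate-specific when a baseline carbon
    source (sucrose) is shifted to challenge substrates such as acetate,
    succinate or glycerol. A synthetic transposon-library simulator with
    known ground-truth fitness supports end-to-end validation, including
    noise-free expected-count output under which the estimator is exactly
    invertible.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'annotation-io.R'
    'cascade.R'
    'fitness.R'
    'report.R'
    'synthetic.R'
    'tnfit-package.R'
    'utils.R'
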