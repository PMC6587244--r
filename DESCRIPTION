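Package: cazymine
Title: Metatranscriptomic CAZyme Annotation and Cellulase Mining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mining carbohydrate-active enzymes (CAZymes),
    especially cellulases of the glycoside hydrolase families, from
    metatranscriptome assemblies of herbivore gut microbiomes. Implements
    BLAST coverage-ratio (BCR) filtering and CAZy family assignment,
    lowest-common-ancestor taxonomic binning, k-mer pseudo-mapping with
    FPKM quantification, six-frame open reading frame prediction with
    Pfam-style domain screening at gathering thresholds, phylogeny-guided
    selection of validation candidates with RT-PCR primer design, and
    analysis of colorimetric enzyme assays (activity calls, specific
    activity in U/mg, temperature and pH optima, residual activity).
    A synthetic-data module generates ground-truthed communities,
    unigenes with planted cellulase ORFs, hit tables, fragment counts
    and assay plates so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
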