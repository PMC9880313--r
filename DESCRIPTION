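Package: stopfate
Title: NMD-Aware Annotation of Premature Termination Codon Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Re-annotates coding variants that introduce a premature
    termination codon (PTC). Instead of reporting every stop-gained or
    frameshift variant as a protein truncation, the package locates the PTC
    on the exon scaffold of the transcript and applies nonsense-mediated
    decay (NMD) escape rules (the 50 nt penultimate-exon rule, the
    last-exon rule, the 150 nt start-proximal rule and the 400 bp long-exon
    rule) to decide whether the predicted outcome is a degraded transcript
    (missing RNA / missing protein) or a genuinely truncated protein. Emits
    corrected HGVS r./p. strings (including r.(0)/p.(0)) and Variation
    Ontology (VariO) terms, tags predicted loss-of-function variant types,
    and flags apparently-synonymous substitutions at splice-critical exonic
    positions as candidate unsense variants.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: VariantAnnotation, Sequencing, Software
RoxygenNote: 7.3.3
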