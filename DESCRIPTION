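Package: mitoEmbryo
Title: Mitochondrial DNA Quantification and Viability Thresholding for
    Embryo Biopsies
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative machinery linking the mitochondrial DNA content
    of preimplantation embryo biopsies to maternal age, aneuploidy and
    implantation potential. Implements 2^-ddCt relative quantification of
    mtDNA against a multicopy Alu target from triplicate qPCR cycle
    thresholds, a bin-based shallow-sequencing copy-number caller with GC
    stratified-median normalization and 13-bin sliding-median smoothing,
    an NGS mitochondrial-fraction measure with pileup-based heteroplasmy
    estimation, a viability-threshold classifier with retrospective
    derivation and blinded prospective evaluation, and cohort-level group
    comparisons. A synthetic-cohort generator emulates the statistical
    structure of trophectoderm biopsy data so the full pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools
biocViews: CopyNumberVariation, Sequencing, QualityControl, Preprocessing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'cnv.R'
    'cohortStats.R'
    'grid.R'
    'io.R'
    'mito.R'
    'viability.R'
    'qpcr.R'
    'simulate.R'
    'pipeline.R'
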