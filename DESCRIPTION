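Package: dualTat
Title: Screening Polytopic Membrane Proteins for Dual Sec/Tat Targeting
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate dual Sec/Tat-targeted polytopic membrane
    proteins in protein FASTA input. Combines twin-arginine (RR) motif
    detection with transmembrane-domain counting and orientation filters
    (positive-inside charge bias or imported TMHMM-style predictions), and
    computes the apparent free energy of translocon-mediated membrane
    insertion (dG_app) of candidate helices under a configurable biological
    hydrophobicity scale. A Sec-release feature rubric reports final-TMD
    hydrophobicity, C-terminal positive charges, cytoplasmic loop length and
    leucine what-if substitution deltas. Includes a seeded synthetic protein
    generator with ground-truth topologies for end-to-end validation, TSV and
    GFF3 result writers, and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Software, SequenceMatching, Proteomics, MembraneProteins
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'seqio.R'
    'dgscale.R'
    'topology.R'
    'synth.R'
    'tatmotif.R'
    'dualscreen.R'
    'secfeatures.R'
    'pipeline.R'
    'cli.R'
    'methods-accessors.R'
    'zzz.R'
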