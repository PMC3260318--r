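Package: mtrecomb
Title: Repeat-Mediated Recombination and Structural Analysis of
    Multichromosomal Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the structure of multichromosomal circular
    organelle genomes from paired-end sequencing data: detection and
    characterisation of dispersed repeats by genome self-comparison,
    quantification of repeat-mediated recombinant genome conformations from
    discordant read-pair mappings (with a reversed-orientation control),
    chromosome-autonomy and read-depth evenness reports, homology-based
    classification of intergenic sequence, and a census of species-unique
    indels from multiple alignments. Includes a ground-truthed simulator of
    circular multichromosomal genomes, recombinant conformations, and
    paired-end read libraries for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
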