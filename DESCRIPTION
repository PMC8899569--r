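Package: alleleEditR
Title: Allele-Specific CRISPR Amplicon Editing Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying allele-specific CRISPR/Cas9 editing from
    amplicon deep sequencing in heterozygous disease models where the mutant
    allele is phased with a silent marker base. Provides a two-allele amplicon
    reference class, SpCas9 guide (protospacer/NGG PAM) enumeration with
    cut-site annotation, glocal read alignment with marker calling and
    cut-site indel classification under an out-of-frame 1-8 bp rule,
    T7 endonuclease I densitometry conversion to variant frequency,
    ABR-based hearing-improvement categorization and efficacy-phenotype
    correlation, and thallium-flux (FluxOR) fluorescence trace quantification
    (delta-F/F0 and influx slope). Includes seeded synthetic-data generators
    with ground-truth tables for validation of every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
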