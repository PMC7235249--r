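Package: pamprospector
Title: Discovery and Characterization of Cas9 PAM Specificity from
    Sequence and Biochemical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for inferring and characterizing the
    protospacer adjacent motif (PAM) specificity of Cas9 orthologs. Mines
    ortholog protein sets for divergence at PAM-contacting residues, maps
    CRISPR spacers to phage genomes to infer PAM consensus motifs from
    protospacer flanks (position frequency matrices, information content,
    IUPAC consensus), analyzes reporter-sort trace enrichment over
    randomized PAM libraries, quantifies in vitro cleavage from gel band
    intensities (NAAN matrices, first-order kinetics, titrations), and
    computes genome PAM-landscape statistics. A seeded synthetic-data
    module generates inputs with known truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
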