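Package: chimeraMSA
Title: Windowed Multiple Sequence Alignments for Chimeric Fusion Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds structure-predictor inputs for chimeric (fusion)
    proteins by the windowed multiple sequence alignment strategy:
    alignments are computed independently for a scaffold protein and a
    fused peptide tag and then merged into a single block-diagonal,
    gap-padded alignment over the chimeric query, so that each region
    keeps its own homology signal. Also provides fusion-construct
    assembly and enumeration with a flexible Gly-Ser linker, greedy
    redundancy clustering at identity and bidirectional-coverage
    thresholds, A3M/aligned-FASTA input and output in the
    MMseqs2/ColabFold dialect, and per-region evaluation of predicted
    structures (Kabsch superposition RMSD and mean pLDDT over a residue
    window), together with synthetic alignment and coordinate
    generators for fully offline testing and demos.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    bio3d,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
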