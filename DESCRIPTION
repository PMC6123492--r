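Package: sdntrim
Title: Small RNA 3' Trimming: Profiler, Exonuclease Simulator and Structure Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying 3'->5' exonucleolytic trimming of small RNAs by
    DEDDh nucleases of the SDN family. Provides a 5'-anchored isomiR profiler
    that classifies small-RNA reads against mature miRNA references into
    3'-truncation and 3'-tailing states and computes truncated-to-full-length
    (TR/FL) ratios and truncation-by-tailing proportion matrices; a stochastic
    rule-based simulator of SDN1-style trimming on single-stranded RNA,
    miRNA/target duplexes and AGO-bound miRNAs, with a synthetic sRNA-seq
    library generator carrying ground truth; structure analysis of
    protein-RNA complexes (Shrake-Rupley solvent-accessible surface area,
    buried interface areas, protein-RNA contact maps, ion occupancies, model
    statistics); and weighted-average NMR chemical-shift-perturbation scoring
    for titration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
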