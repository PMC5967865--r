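Package: sybodykit
Title: Design and Analysis Toolkit for Synthetic Nanobody (Sybody) Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the computational side of synthetic single-domain
    antibody (sybody) selection campaigns. Models trinucleotide-mix codon
    randomization schemes for the three sybody libraries (concave, loop,
    convex), computes exact theoretical library diversities and samples
    in-silico library members; simulates Type IIS restriction digestion,
    sticky-end ligation and the two-step CDR assembly, including
    fragment-exchange (FX) cloning overhang validation; quantifies selection
    enrichment from qPCR standard curves and models diversity bottlenecks
    through a ribosome-display/phage-display selection cascade; and fits the
    platform's four binding and stability models (1:1 interaction kinetics,
    Schild allosteric competition, hyperbolic IC50 inhibition and Boltzmann
    melting curves). A synthetic-data generator produces every input the
    analysis functions consume, with declared parameters and seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
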