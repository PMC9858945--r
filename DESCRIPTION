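Package: ctxsub
Title: Context-Dependent Substitution Analysis of Coding and Noncoding DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers nucleotide substitutions from triplets of closely related
    homologous sequences conditioned on the flanking tetranucleotide context,
    builds per-context Markov transition matrices and their stationary
    (equilibrium) base compositions, and compares substitution dynamics
    between fourfold-degenerate third codon positions and intergenic
    noncoding sites: rates by substitution class, equilibrium A+T content,
    compositional skews, hexanucleotide-weighted predictions, and the CpG
    deamination (CG) effect. Includes a neighbour-dependent sequence
    evolution simulator so that every pipeline stage is verifiable by
    parameter recovery, bootstrap resampling of count matrices, and a
    plain-file pipeline driver for deterministic reruns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
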