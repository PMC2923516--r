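Package: tetmat
Title: Allelic Divergence, Gene Conversion and Recombination Suppression on
    Neurospora tetrasperma Mating-Type Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for the comparative analysis of fungal
    mating-type (mat) chromosomes in the self-fertile ascomycete Neurospora
    tetrasperma. Computes per-gene allelic divergence between mat A- and mat
    a-linked alleles (Nei-Gojobori dN/dS with Jukes-Cantor correction and
    intron polymorphism counts), builds per-gene genealogies with
    neighbor-joining and nonparametric bootstrap, calls allele phase
    (together/separated) for each chromosome pair, demarcates the
    recombinationally suppressed region per lineage, detects gene-conversion
    and crossover events from ordered gene genealogies, and estimates per-site
    homogenization rates r = K/(2T). Includes a forward-time sequence
    simulator with planted conversion and crossover events so that every
    stage can be exercised and validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
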