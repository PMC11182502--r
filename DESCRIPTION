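Package: uniparental
Title: Population Structure Analysis of Uniparental Markers (mtDNA and MSY)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genetic analysis of uniparentally inherited
    markers: masking of complete-mitogenome alignments (hypervariable
    poly-C/repeat regions, N- and gap-containing columns), collapsing of
    sequences and Y-SNP genotypes into haplotype tables, Nei (1987) haplotype
    and nucleotide diversity with variances and mean pairwise differences,
    within/between-population identical-haplotype sharing proportions,
    AMOVA-based pairwise PhiST with permutation tests, non-metric
    multidimensional scaling of distance matrices, correspondence analysis of
    haplogroup frequency tables, and a forward-time Wright-Fisher simulator of
    sex-biased (matrilocal/patrilocal) migration for studying the expected
    contrast between maternal and paternal diversity under different
    postmarital residence rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
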