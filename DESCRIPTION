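Package: IGHGpop
Title: Allele Catalogs, Gm Allotype Typing and Population Genetics of the
    Immunoglobulin Heavy Constant Gamma Gene Segments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Data structures and analysis methods for nucleotide-level
    diversity of the immunoglobulin heavy constant gamma gene segments
    (IGHG1, IGHG2, IGHG3). Ships a machine-readable catalog of exonic
    variant sites and named alleles with serological Gm allotype
    annotations, assigns allele pairs to individuals from unphased
    per-site genotype calls with novel-allele detection and phase
    ambiguity classification, and maps alleles and three-segment allele
    haplotypes to Gm allotype haplotype strings. Implements the
    population-genetic toolbox used to analyse such data: direct-count
    allele frequencies, the Guo-Thompson exact test of Hardy-Weinberg
    equilibrium, EM haplotype frequency estimation across segments,
    pairwise linkage disequilibrium (D, D', r2), Weir-Cockerham-type
    pairwise FST, the Raymond-Rousset exact test of population
    differentiation, principal component analysis of allotype haplotype
    frequencies, median-joining allele networks, site-frequency-spectrum
    neutrality statistics (Tajima's D, Fu and Li's D/F/D*/F*, Fay and
    Wu's H) with coalescent-simulation null distributions, and
    Nei-Gojobori synonymous/non-synonymous analysis with a codon-based
    Z-test of selection. A synthetic-data module simulates diploid
    genotype tables under Hardy-Weinberg proportions from per-population
    allele or haplotype frequencies and neutral alignments with an
    outgroup, so every analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
biocViews: Genetics, PopulationGenetics, SNP, Immunology, Software
RoxygenNote: 7.3.3
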