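Package: dronemap
Title: Crossover Mapping, Genetic-Map Scaffolding and Structural-Variant
    Genotyping from Haploid Drone Meioses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing honey bee genomes through the meioses of
    haploid drones. Queen-heterozygous SNPs genotyped in colonies of drones
    are turned into genotype vectors, grouped into crossover-free bins,
    phased by recombination minimisation and cleaned of short non-crossover
    gene-conversion tracts. Contig end vectors are then used to order and
    orient assembly contigs into chromosomes by minimising recombination
    events, giving a genetic map, windowed recombination-rate tracks and a
    diagnostic for mis-assembly-induced artefactual recombination hotspots.
    Companion modules classify tandem-repeat arrays (the 91 bp and 371 bp
    honey bee families, telomeric TTAGG arrays, AluI/AvaI marker loci),
    canonicalise repeat monomers by rotation, and genotype presence/absence
    structural variants in haploid samples from sequencing-depth ratios with
    exact one-dimensional 2-means clustering. A seeded simulator generates
    colonies, meioses, fragmented contigs, repeat arrays and depth tracks
    with truth sets for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
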