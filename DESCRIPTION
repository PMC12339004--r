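Package: mitesweep
Title: Pool-Seq Sweep Scans and Target-Site Resistance Genetics for Spider Mites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the rapid evolution of acaricide resistance in
    the haplodiploid two-spotted spider mite (Tetranychus urticae): pooled
    whole-genome diversity estimators (nucleotide diversity, Watterson's
    theta, Tajima's D, pairwise FST at uniform subsampled depth), population
    branch statistic / population branch excess selective-sweep scans,
    probit dose-response LC50 estimation with Abbott control-mortality
    correction, codon-level annotation of target-site mutations in the
    succinate dehydrogenase subunit genes sdhB and sdhD, haplotype
    resolution from Sanger genotypes with minimum-spanning haplotype
    networks and single-crossover recombinant enumeration, selection
    coefficient estimation from allele-frequency trajectories, and the
    recurrent-mutation Theta = 3 * Ne * mu calculation. Includes a forward
    haplodiploid Wright-Fisher simulator that generates pooled read counts,
    Sanger-style genotypes and bioassay mortality tables with known ground
    truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    vegan,
    geosphere,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
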