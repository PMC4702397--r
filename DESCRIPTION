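Package: rilmap
Title: Bin Maps, Genetic Maps, Scaffold Anchoring and QTL Scans for
    Recombinant Inbred Line Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational core of a recombinant inbred line
    (RIL) genotyping-by-sequencing study: coding and filtering of biallelic
    SNP genotypes against two inbred parents, sliding-window bin-genotype
    calling and recombination-breakpoint detection, population bin-map
    construction, two-point linkage mapping with the Kosambi mapping
    function, genetic-map-guided scaffold anchoring and chimeric-scaffold
    splitting into AGP/FASTA pseudomolecules, Haley-Knott and composite
    interval mapping QTL scans with genome-wide permutation thresholds, and
    descriptive trait genetics (heritability, correlations, transgressive
    segregation).  A forward simulator of biparental single-seed-descent RIL
    populations with a full truth set makes every stage verifiable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
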