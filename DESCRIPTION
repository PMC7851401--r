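Package: joindel
Title: Joint Deletion Calling from Paired-End Insert-Size Profiles
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and genotypes medium-size deletions (roughly 500 bp to 10 kb)
    jointly across many short-read genomes. Each coordinate-sorted alignment file is
    first reduced to a compact, indexed insert-size profile. The profiles of all
    samples are then scanned together in small genomic windows with a weighted
    likelihood-ratio test in which deletion length and population allele frequency
    are estimated iteratively, so that rare carriers are boosted and noncarriers are
    down-weighted. Significant windows are merged into nonredundant calls and written
    as a multi-sample VCF with PHRED-scaled genotype likelihoods. The package ships a
    cohort simulator (deletion sets, haplotypes, diploid genotypes, read-pair
    streams) and an evaluation suite covering call-set matching by reciprocal
    overlap, Hardy-Weinberg filtering, Mendelian inheritance error and transmission
    rates in trios, and de novo deletion screening.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite
Config/testthat/edition: 3
biocViews: StructuralVariation, VariantDetection, Genetics, Sequencing
RoxygenNote: 7.3.3
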