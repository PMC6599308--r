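Package: pedr
Title: Polymorphic Edge Detection from Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects polymorphisms from next-generation sequencing short reads
    by locating polymorphic edges, the first mismatched base between two
    homologous sequences. Two complementary callers are provided: a
    reference-free k-mer method that compares (k-1)-mer last-base count
    tables between a target and a control read set to call SNP edges, and a
    bidirectional alignment method that anchors both ends of each read on a
    genome-unique k-mer index and scans inward to call SNPs, insertions,
    deletions, inversions and translocations. Candidate calls are verified
    by counting reads that carry the wild-type or mutant sequence context,
    yielding homozygous/heterozygous genotypes. A planted-mutation simulator
    generates artificial genomes, truth tables and sliced reads for
    end-to-end evaluation, and a bin classifier summarises shared and
    sample-specific SNPs along chromosomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
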