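Package: fiveprime
Title: Reduced mRNA Secondary-Structure Stability Near the Translation-Initiation Site
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-scale analysis of local mRNA secondary-structure stability
    downstream of the start codon. Computes sliding-window minimum-free-energy
    folding energies for coding sequences, compares them against synonymous-codon
    permutation nulls (codon shuffle and dinucleotide-preserving dicodon shuffle)
    via Z-scores of folding energy and GC content, aggregates per-genome window
    profiles, and provides comparative statistics across and within genomes:
    Spearman correlations with genomic GC content and optimal growth temperature,
    effective number of codons (ENC), top/bottom stratification of genes by GC,
    codon bias and expression, and principal component regression. Includes a
    synthetic multi-species coding-sequence generator with a tunable 5'
    destabilization signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
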