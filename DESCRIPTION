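Package: mateseq
Title: Comparative Floral Transcriptomics of Outcrossing and Selfing Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for comparing floral transcriptomes of
    outcrossing and selfing genotypes assembled de novo from short reads.
    Builds a consensus reference transcriptome from per-sample contig sets via
    reciprocal-best-hit ortholog grouping, redundancy collapse, consensus
    extension and protein-guided fragment joining; maps reads back to the
    reference to call diploid genotypes with a Bayesian pileup caller and
    Phred-scaled consensus qualities; screens loci for paralogy using residual
    heterozygosity in selfers; estimates pairwise SNP divergence and
    Watterson's theta over a conservative locus set; quantifies expression as
    FPKM with bootstrap correlation confidence intervals, count-based
    differential expression with Benjamini-Hochberg FDR control, and Fisher's
    exact GO-term enrichment. Includes a synthetic-data generator that
    emulates the study design (one heterozygous outcrosser, two independently
    derived selfers, one selfing outgroup) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
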