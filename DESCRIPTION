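Package: matrixphase
Title: Diploid Haplotype Assembly by Low-Rank Matrix Completion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles the two haplotypes of a diploid individual from aligned
    sequencing fragments by casting phasing as a low-rank matrix completion
    problem. Fragments are encoded as a sparse reads-by-SNPs matrix with
    entries +1 (wild allele) and -1 (rare allele); the matrix is completed
    under a rank-2 (rank-1 for all-heterozygous sites) model with one of
    three solvers (iterative singular value thresholding, nuclear-norm
    minimization via Douglas-Rachford splitting, or an OPTSPACE-style
    trim/project/clean scheme), and the haplotype pair is read off the
    completed matrix by reduced-row-echelon pivot selection and sign
    quantization. Includes haplotype-block partitioning for disconnected
    real-style data, evaluation metrics (reconstruction rate, switch error
    rate with short/long classification, SNP missing rate, block length
    statistics and adjusted N50), and a seeded simulator of paired-end
    read matrices for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
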