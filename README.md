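# matrixphase

Diploid haplotype assembly by low-rank matrix completion.

`matrixphase` reconstructs the two haplotypes of a single diploid
individual from aligned sequencing fragments. It is aimed at method
developers and analysts who work with SNP-level fragment files
(HapCUT-style fragment format or plain triplet tables) and want a
transparent, fully scriptable phasing pipeline with built-in evaluation
and simulation.

## The model

Code the wild allele at each bi-allelic SNP as +1 and the rare allele as
−1, stack one read per row, and zero-fill unobserved sites: this gives a
sparse read matrix *R* ∈ {−1, 0, +1}^(N×l) with observed-cell set Ω. In
the error-free case every row of the underlying complete matrix is one
of the two haplotype vectors h_m, h_p ∈ {±1}^l, so the complete matrix
has rank ≤ 2 (rank 1 if every site is heterozygous, since then
h_m = −h_p). Phasing becomes matrix completion:

    min_H  Σ_{(i,j)∈Ω} (H_ij − R_ij)²   s.t.  rank(H) = r,  r ∈ {1, 2}

followed by sign quantization and extraction of two representative rows
via the pivots of the reduced row echelon form of Hᵀ. Three solvers are
provided:

* `complete_svt()` — iterative singular value thresholding,
  X^k = D_τ(Y^{k−1}), Y^k = Y^{k−1} + δ·P_Ω(R − X^k);
* `complete_nuclear()` — nuclear-norm minimization
  min ‖H‖\* s.t. ‖P_Ω(H − R)‖_F ≤ ε, solved by Douglas–Rachford
  splitting;
* `complete_optspace()` — OPTSPACE-style trim / rank-r spectral
  projection / least-squares cleaning with block-coordinate gradient
  descent on the factors.

Disconnected read–SNP components are phased independently as haplotype
blocks (`partition_blocks()`), and the evaluation module implements the
reconstruction rate, switch error rate with short/long classification,
SNP missing rate, and block statistics including the adjusted N50
(AN50). A seeded simulator of paired-end fragment matrices
(`simulate_truth()`, `simulate_reads()`, `add_read_noise()`,
`run_benchmark()`) makes every stage testable without any external
data.

## Worked example

The package ships a 10-SNP, 10-read example (the β2AR gene region) as
plain-text fixtures:

```r
library(matrixphase)
sites <- read_site_map(system.file("extdata", "beta2ar_sites.tsv", package = "matrixphase"))
frags <- parse_fragments(system.file("extdata", "beta2ar_reads.frag", package = "matrixphase"))
rm <- build_read_matrix(frags, l = 10)
rm
#> <read_matrix> 10 reads x 10 SNP sites, 45 observed cells

phasing <- hap_assemble(frags, l = 10, solver = "optspace")
phasing
#> <hap_phasing> solver=optspace, l=10, 1 block(s), 10 reads used (0 dropped), 0 unphased SNP(s)
decode_haplotype(phasing$h1, sites)
#> [1] "ACGGCCCGGG"

truth <- read_truth_haplotypes(system.file("extdata", "beta2ar_truth.tsv", package = "matrixphase"))
hap_evaluate(phasing, truth, sites)
#> <hap_eval>
#>   reconstruction rate  1.0000
#>   switches             0 (SWER 0.0000; 0 short, 0 long)
#>   SNP missing rate     0.0000
#>   blocks               1 (mean span 9001.0 bp, AN50 4950.55 bp)
```

All 45 observations are phased into a single block; the better-matched
strand reproduces the true maternal haplotype exactly (reconstruction
rate 1, no switches, nothing missing). Two of the ten reads observe
only sites at which the two haplotypes are opposite, so their completed
rows are not fully determined by a rank-2 fit — the second extracted
strand can disagree with the truth at the two sites where the
haplotypes agree, which is what depresses the correctness-weighted AN50
here; the methods vignette discusses this under-determination in
detail.

A simulated benchmark cell (700 SNPs, 561 paired-end reads averaging
7.4 SNPs each, 10% of observed entries contaminated by uniform noise,
5 trials):

```r
run_benchmark(l = 700, n_reads = 561L, error_rates = 0.1, trials = 5, seed = 1)
#>   n_reads coverage error_rate   solver mean_rr   se_rr mean_swer se_swer
#> 1     561     5.93        0.1 optspace    0.99 0.00153    0.0131 0.00368
```

About 99% of the 700 alleles are phased correctly and roughly 9
switches occur per trial (SWER 0.013).

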