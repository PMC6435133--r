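---
title: "Haplotype assembly as low-rank matrix completion: model, solvers, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype assembly as low-rank matrix completion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matrixphase)
```

## The model

A diploid individual carries two haplotypes, the sequences of alleles on
the maternal and paternal copies of a chromosome.  Sequencing reads each
observe a handful of nearby SNPs of one (unknown) parental copy.  At a
bi-allelic SNP we code the common ("wild") allele as $+1$ and the rare
allele as $-1$.  Stacking one read per row and zero-filling unobserved
sites gives the read matrix $R \in \{-1,0,+1\}^{N\times l}$ with observed
index set $\Omega$ (the nonzero pattern).

Without sequencing errors, every row of the underlying complete matrix
$H$ equals one of the two haplotype vectors $h_m, h_p \in \{\pm1\}^l$,
so $\mathrm{rank}(H) \le 2$; when every site is heterozygous,
$h_m = -h_p$ and the rank is 1.  Haplotype assembly is cast as the
completion problem

$$\min_H \sum_{(i,j)\in\Omega} (H_{ij} - R_{ij})^2
  \quad\text{s.t.}\quad \mathrm{rank}(H) = r,\qquad r \in \{1,2\},$$

followed by quantizing $H$ back to signs and reading off two
representative rows.  Errors enter as sign flips of observed entries;
the low-rank fit averages them out.

## The three solvers

**Singular value thresholding** (`complete_svt()`) iterates
$X^k = D_\tau(Y^{k-1})$, $Y^k = Y^{k-1} + \delta\,P_\Omega(R - X^k)$
from $Y^0 = R$, where $D_\tau$ shrinks every singular value by $\tau$
(the proximal operator of $\tau\|\cdot\|_*$) and $P_\Omega$ zeroes
unobserved cells.  It stops when
$\|P_\Omega(X^k - R)\|_F \le \varepsilon\|R\|_F$.  Defaults:
$\tau = 5\sqrt{Nl}$, $\varepsilon = 10^{-4}$, and
$\delta = \min(1.2\,Nl/|\Omega|,\ 1.9)$.  The $1.2/\text{sampling
ratio}$ step is the usual choice for sparsely observed matrices, but the
fixed-point iteration on the observed cells is contractive only for
$\delta < 2$ (the shrinkage operator is 1-Lipschitz); on densely
observed matrices the uncapped value exceeds 2 and the residual
oscillates indefinitely, hence the cap.

**Nuclear-norm minimization** (`complete_nuclear()`) solves the convex
surrogate
$\min_H \|H\|_*\ \text{s.t.}\ \|P_\Omega(H - R)\|_F \le \epsilon$
by Douglas–Rachford splitting: the prox of the nuclear norm is singular
value shrinkage, and projection onto the constraint ball is closed-form
on the observed cells.  $\epsilon$ defaults to $10^{-3}\|R\|_F$
(near-interpolation); for noisy data it should be set near the expected
noise norm on $\Omega$.  The splitting scale $\gamma$ defaults to
$\|R\|_F/\sqrt{\min(N,l)}$, the size of a typical singular value.

**OPTSPACE** (`complete_optspace()`) assumes the rank known and runs
three steps: (a) *trim* rows/columns whose degree exceeds twice the
average (they would dominate the spectrum), (b) *project*: the top-$r$
SVD of the trimmed matrix rescaled by $Nl/|\Omega|$ to undo the
zero-fill bias, and (c) *clean*: minimize the observed-cell squared
error over factors $X S Y^\top$, solving the $r\times r$ core $S$
exactly (least squares, via SVD pseudoinverse so factor degeneracies
stay bounded) and descending on the orthonormal factors.  The descent is
block-coordinate — one backtracking gradient step on $X$, then on $Y$,
each followed by QR re-orthonormalization and an exact re-solve of $S$ —
because a simultaneous step on both factors was observed to stall in
spurious stationary points that the alternating scheme walks out of.
The objective trace is non-increasing by construction.  Stopping needs
three consecutive slow iterations (relative decrease below `tol`):
descent can crawl past a saddle before accelerating again, and a single
slow step is not evidence of convergence.  The cleaning objective runs
over the original $\Omega$; trimming only shapes the initialization
(`clean_on_trimmed = TRUE` restricts it instead).

## Extraction

On the completed matrix, the first two pivot positions of the reduced
row echelon form of $H^\top$ identify the first two linearly independent
rows — the two haplotype representatives — which are quantized to signs
(`extract_haplotypes()`).  Three numerical choices matter.

* *Pivot tolerance* (default $10^{-2}$ relative to the largest entry).
  It must sit **above** the solvers' convergence tolerances: iterates
  carry residuals up to about $10^{-3}$ of the matrix scale, and a
  tighter pivot tolerance declares numerically identical rows
  independent, handing back a junk second haplotype.  A genuinely
  independent row has $O(1)$ residual, two orders of magnitude away.
* *Zero band* (default 0): entries inside $[-z, z]$ quantize to missing
  rather than to an allele.  Exact zeros — e.g. whole columns no read
  observes — always decode to missing; forcing them to an allele would
  fabricate calls and corrupt the SNP missing rate.
* *Consensus mode* (off by default): the pivot-row rule is exact on a
  noiseless low-rank completion but fragile under noise, because the
  first row to look independent is often precisely a read carrying
  errors.  With `consensus = TRUE` each haplotype is re-estimated as the
  majority sign over all rows clustered to its pivot, out-voting
  isolated read errors.  The default stays with the plain pivot rule.

A caveat worth knowing: when a read observes only sites at which the two
haplotypes are opposite (e.g. only heterozygous sites, in a matrix that
also contains homozygous ones), its row restricted to those columns is
compatible with *both* haplotype directions, and its completed values at
the remaining sites are not determined by any rank-2 fit — different
solvers legitimately return different signs there.  The bundled 10-read
worked example contains two such reads; its completion is consequently
non-unique at four cells, and the quantized completion can gain a third
distinct row pattern even though the unquantized completion has exact
rank 2.  This is a property of the data, not of a solver.

## Blocks

Two SNPs can only be phased relative to each other if a chain of reads
links them, each read covering at least two SNPs.  `partition_blocks()`
computes the connected components of that graph and `hap_assemble()`
completes each block independently — a rank model cannot link
disconnected components, and the relative phase between blocks is
arbitrary.  Reads covering fewer than `min_snps` (default 2) SNPs are
dropped first; a 1-SNP read cannot phase anything.

## Evaluation metrics

* **Reconstruction rate**:
  $rr = 1 - \min\{HD(\hat h_m, h_m),\ HD(\hat h_p, h_p)\}/l$, after
  assigning the estimate's interchangeable labels by total-distance
  minimization.  The Hamming distance counts missing vs. called as a
  mismatch.  For multi-block phasings the label assignment is made per
  block (each block's labels are independently arbitrary), per-strand
  distances accumulate over blocks, and unphased SNPs count as errors.
* **Switch error rate**: between consecutive heterozygous truth sites at
  which the estimate is phased, a switch is a change in which parent the
  estimate tracks; SWER divides the switch count by $l$.  Runs of
  flipped agreement of length 1 (an isolated mismatched site, i.e. a
  switch in and immediately back) classify as one *short* switch; runs
  of length $\ge 2$ as one *long* switch.  Homozygous truth sites are
  excluded (parental origin is undefined there); blocks restart the
  labeling.
* **SNP missing rate**: the fraction of all $l$ SNPs with no call in
  either estimated haplotype, including SNPs in no block.
* **Block statistics**: mean block span, and AN50 — each block's span is
  weighted by its fraction of correctly phased alleles, blocks are
  sorted by adjusted span, and the AN50 is the adjusted span at which
  the running sum first reaches half the total unadjusted span.  Spans
  are in bp when a site map is given (last minus first position plus
  one), otherwise in SNPs and labeled as such.

## The simulator and the benchmark conditions

`simulate_truth()` draws $h_1$ uniformly over $\{\pm1\}^l$; by default
every site is heterozygous ($h_2 = -h_1$), matching the heterozygous-
site matrices used in standard haplotype-assembly benchmarks (homozygous
sites are ordinarily not part of fragment data at all).  Under this
default the natural model rank is 1, and `run_benchmark()` accordingly
solves at rank 1 unless told otherwise.

`simulate_reads()` emulates paired-end fragments: a read observes $k$
SNPs, with $k$ mixed over $\{\lfloor\bar k\rfloor, \lceil\bar k\rceil\}$
so the mean is $\bar k$ (default 7.4), split into mates of
$\lceil k/2 \rceil$ and $\lfloor k/2 \rfloor$ consecutive SNPs separated
by a geometric gap.  The gap mean defaults to 100 SNPs, i.e. long-insert
mate-pair/fosmid-scale libraries.  This is the one geometry parameter
with real leverage and deserves its own justification: with a short gap
the observation pattern is a narrow band around the diagonal and carries
almost no long-range phase information — the spectral initialization
localizes, sign domains form, and *no* solver can reach the accuracy
that the same number of observations supports under long-range linking
(we verified that even initializing the cleaning step at the generating
haplotypes does not close the gap).  Long-insert libraries are exactly
how low-coverage phasing is made well-posed in practice.

`add_read_noise()` supports two error models: `"uniform"` (default), in
which a fraction $e$ of the observed cells is contaminated by a uniform
random sign — so a contaminated cell flips with probability $1/2$ and
the effective flip rate is $e/2$ — and `"flip"`, which flips each cell
with probability $e$.  The uniform-contamination reading is the
benchmark default; a simple decoding-limit argument supports it: at the
benchmark's own read counts the per-column coverage is about 5.9, and
majority decoding under a literal 20% flip rate could not exceed
$rr \approx 0.94$, below what such benchmarks report, whereas 20%
uniform contamination (10% effective flips) supports
$rr \approx 0.99$.

The benchmark grid used by `scripts/acceptance.R` and the test suite:
$l = 700$, $N \in \{561, 936, 1873\}$ (nominal coverages 3, 5, 10),
contaminated fractions 10% and 20%, OPTSPACE at rank 1, scored by
reconstruction rate and SWER against the generating pair, averaged over
20–25 seeded trials per cell (the package's choice of replication; a
master seed spawns per-trial sub-seeds so any trial is reproducible in
isolation).

### What the simulator does and does not emulate

Truth haplotypes are uniform random signs, not real haplotypes: under
the rank model the solvers' behaviour depends on the observation pattern
and the noise, not on haplotype content, but any structure in real data
that correlates errors with haplotype content (allelic bias, mapping
error near indels) is outside the model.  Base qualities, indels and
mapping errors are not simulated, and the noise is independent across
cells.  Passing the benchmark therefore demonstrates correct behaviour
under the model's own assumptions, not performance on any particular
real dataset.

### Study conditions of the exact-recovery property suite

Noiseless exact recovery (all three solvers return the generating
matrix bit-exactly after quantization) is asserted over randomly
generated instances that satisfy the conditions under which recovery is
information-theoretically possible:

* every read covers at least one heterozygous and one homozygous site
  (a read seeing only one kind observes collinear restrictions of the
  two haplotypes and its row is under-determined);
* the graph on heterozygous sites, with edges between het sites
  co-covered by a read, is connected (relative phase propagates only
  through such reads; homozygous sites are pinned individually);
* every column is observed by reads of **both** parents (a haplotype's
  allele at a column no read of its parent observes is not determined
  by any rank-2 fit — an alternative exact completion exists);
* reads sample random site subsets, so the observation pattern has no
  unobserved corners (contiguous-only reads leave corner cells whose
  nuclear-norm-minimal value is near zero rather than $\pm1$).

Each condition was added after constructing an explicit counterexample
without it.  On small noisy instances the quantized output of the
continuous solvers does not always coincide with the exhaustive-search
minimizer over sign matrices: the continuous fit can reach a lower
least-squares objective than any sign configuration by tilting the
factors, and the discrepancy is genuine, not an implementation artifact.

## Known limitations

* The pivot-row extraction degrades when the completed matrix is far
  from rank 2 (converged nuclear-norm solutions under noise are
  typically rank 3+); consensus mode mitigates but does not remove this.
* Reads observing only heterozygous sites in a mixed het/hom matrix are
  under-determined (see above); their completed rows are solver-biased.
* The nuclear-norm solver's per-iteration SVD makes it impractical
  beyond a few hundred thousand cells; it enforces a size cap and is
  meant for per-block use.
* Ranks above 2 (polyploidy) and quality-weighted observation models
  are out of scope.
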