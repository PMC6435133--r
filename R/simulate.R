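#' Simulate a truth haplotype pair
#'
#' `h1` is uniform over \{+1, -1\}^l.  At heterozygous sites `h2 = -h1`;
#' with `all_het = TRUE` (the default, matching the heterozygous-site
#' matrices of standard haplotype-assembly benchmarks) every site is
#' heterozygous and the pair has rank 1 as a 2-row matrix.  Otherwise each
#' site is heterozygous independently with probability `het_fraction`,
#' homozygous sites having `h2 = h1`.
#'
#' @param l haplotype length, `>= 2`
#' @param all_het force every site heterozygous
#' @param het_fraction per-site heterozygosity probability when
#'   `all_het = FALSE`
#' @param seed optional integer seed
#' @return a [haplotype_pair] (labels not ambiguous: this is ground truth)
#' @export
simulate_truth <- function(l, all_het = TRUE, het_fraction = 0.5, seed = NULL) {
  stopifnot(l >= 2)
  if (!is.null(seed)) set.seed(seed)
  h1 <- sample(c(-1, 1), l, replace = TRUE)
  het <- if (all_het) rep(TRUE, l) else stats::runif(l) < het_fraction
  h2 <- ifelse(het, -h1, h1)
  haplotype_pair(h1, h2, ambiguous = FALSE)
}

# draw one paired-end footprint: k observed SNPs split into mates of
# ceiling(k/2) and floor(k/2) separated by a geometric gap
.draw_read_sites <- function(l, mean_snps, gap_mean) {
  kf <- floor(mean_snps)
  k <- kf + stats::rbinom(1L, 1L, mean_snps - kf)
  k <- max(k, 2L)
  k1 <- ceiling(k / 2); k2 <- k - k1
  repeat {
    g <- if (k2 > 0L) stats::rgeom(1L, 1 / (1 + gap_mean)) else 0L
    span <- k1 + g + k2
    if (span <= l) break
  }
  s <- sample.int(l - span + 1L, 1L)
  if (k2 > 0L) {
    c(s:(s + k1 - 1L), (s + k1 + g):(s + k1 + g + k2 - 1L))
  } else {
    s:(s + k1 - 1L)
  }
}

#' Simulate paired-end reads from a haplotype pair
#'
#' Each read picks a parent haplotype uniformly, then a paired-end
#' footprint: `k` observed SNPs (drawn from \{floor, ceiling\} of
#' `mean_snps` so the mean is `mean_snps`), split into two mates of
#' `ceiling(k/2)` and `floor(k/2)` consecutive SNPs separated by a
#' geometric gap (mean `gap_mean` SNPs), placed uniformly so the footprint
#' fits in `1..l`.  Observed alleles copy the chosen parent (error-free;
#' add noise with [add_read_noise()]).
#'
#' @param pair a [haplotype_pair] (the truth)
#' @param coverage target mean per-SNP coverage `c`; used to derive
#'   `n_reads = round(c * l / mean_snps)` when `n_reads` is not given
#' @param n_reads number of reads (overrides `coverage`)
#' @param mean_snps mean observed SNPs per read (>= 2)
#' @param gap_mean mean mate-gap in SNPs; the default (100) emulates
#'   long-insert mate-pair libraries, whose long-range links are what
#'   makes low-coverage phasing well-posed (a short gap leaves the
#'   observation pattern narrowly banded and the global phase
#'   under-determined)
#' @param seed optional integer seed
#' @return list of [fragment] objects with ids `"sim_1"`, `"sim_2"`, ...
#' @export
simulate_reads <- function(pair, coverage = NULL, n_reads = NULL,
                           mean_snps = 7.4, gap_mean = 100, seed = NULL) {
  l <- length(pair$h1)
  stopifnot(mean_snps >= 2, l >= ceiling(mean_snps))
  if (is.null(n_reads)) {
    if (is.null(coverage)) stop("give either coverage or n_reads")
    n_reads <- round(coverage * l / mean_snps)
  }
  if (!is.null(seed)) set.seed(seed)
  parents <- sample.int(2L, n_reads, replace = TRUE)
  lapply(seq_len(n_reads), function(k) {
    sites <- .draw_read_sites(l, mean_snps, gap_mean)
    h <- if (parents[k] == 1L) pair$h1 else pair$h2
    fragment(paste0("sim_", k), sites, h[sites])
  })
}

#' Contaminate observed entries with noise
#'
#' Two noise models on the observed cells (Omega is unchanged either
#' way):
#'
#' * `"uniform"` (default): a fraction `error_rate` of the observed cells
#'   is contaminated, each contaminated cell being replaced by a uniform
#'   random sign -- so a contaminated cell actually flips with
#'   probability 1/2 and the effective flip rate is `error_rate / 2`.
#'   This is the natural model for "x% of the entries are contaminated by
#'   uniform noise".
#' * `"flip"`: each observed cell independently flips sign with
#'   probability `error_rate`.
#'
#' @param rm a [read_matrix]
#' @param error_rate contaminated fraction (or flip probability), in
#'   `[0, 1)` for `"uniform"`, `[0, 0.5)` for `"flip"`
#' @param model `"uniform"` or `"flip"`
#' @param seed optional integer seed
#' @return a [read_matrix] with the same Omega; attribute `"n_flipped"`
#'   counts cells whose sign actually changed
#' @export
add_read_noise <- function(rm, error_rate, model = c("uniform", "flip"),
                           seed = NULL) {
  model <- match.arg(model)
  p_flip <- switch(model, uniform = error_rate / 2, flip = error_rate)
  stopifnot(error_rate >= 0, p_flip < 0.5)
  if (!is.null(seed)) set.seed(seed)
  m <- rm$mat
  flip <- logical(0)
  if (length(m@x)) {
    flip <- stats::runif(length(m@x)) < p_flip
    m@x <- m@x * ifelse(flip, -1, 1)
  }
  out <- read_matrix(m)
  attr(out, "read_ids") <- attr(rm, "read_ids")
  attr(out, "n_flipped") <- sum(flip)
  out
}

# run one simulated trial and score it; assembly is per haplotype block
# (a rank model cannot link disconnected components of the read-SNP
# graph, and block labels are arbitrary, so metrics align labels per
# block)
.benchmark_trial <- function(l, n_reads, error_rate, solver, rank,
                             all_het, mean_snps, gap_mean, seed) {
  set.seed(seed)
  truth <- simulate_truth(l, all_het = all_het)
  frags <- simulate_reads(truth, n_reads = n_reads, mean_snps = mean_snps,
                          gap_mean = gap_mean)
  rm <- build_read_matrix(frags, l)
  rm <- add_read_noise(rm, error_rate)
  ph <- suppressWarnings(
    assemble_read_matrix(rm, solver = solver, rank = rank))
  est <- haplotype_pair(ph$h1, ph$h2)
  blocks <- lapply(ph$blocks, `[[`, "sites")
  c(rr = reconstruction_rate(est, truth, blocks),
    swer = switch_error_rate(est, truth, blocks, l = l))
}

#' Run the simulated benchmark grid
#'
#' For every combination of read count (or coverage), entry error rate and
#' solver, simulates `trials` independent read matrices (truth pair,
#' paired-end reads, sign-flip noise), runs the solver, extracts the
#' haplotypes and scores them; reports per-cell means and standard errors
#' of the reconstruction rate and switch error rate.  A master seed spawns
#' one sub-seed per trial so any trial is reproducible in isolation;
#' trials where a solver fails are excluded and counted.
#'
#' @param l haplotype length
#' @param n_reads integer vector of read counts per cell (alternatively
#'   give `coverage`, converted via `round(c * l / mean_snps)`)
#' @param coverage numeric vector of coverages (used when `n_reads` is
#'   NULL; also used to label cells)
#' @param error_rates numeric vector of entry error rates
#' @param solvers character vector among `"optspace"`, `"svt"`, `"nuclear"`
#' @param trials trials per cell
#' @param seed master seed
#' @param rank solver rank; `NULL` (default) resolves to 1 when
#'   `all_het = TRUE` (the completed matrix of an all-heterozygous pair
#'   has rank 1 and OPTSPACE assumes the rank known) and 2 otherwise
#' @param all_het,mean_snps,gap_mean simulator settings, see
#'   [simulate_truth()] and [simulate_reads()]
#' @return data frame with one row per (cell, solver): `n_reads`,
#'   `coverage`, `error_rate`, `solver`, `mean_rr`, `se_rr`, `mean_swer`,
#'   `se_swer`, `trials_ok`, `trials_failed`
#' @export
run_benchmark <- function(l = 700L, n_reads = NULL, coverage = NULL,
                          error_rates = c(0.1, 0.2),
                          solvers = "optspace", trials = 20L, seed = 1L,
                          rank = NULL, all_het = TRUE, mean_snps = 7.4,
                          gap_mean = 100) {
  if (is.null(rank)) rank <- if (all_het) 1L else 2L
  if (is.null(n_reads)) {
    if (is.null(coverage)) stop("give n_reads or coverage")
    n_reads <- round(coverage * l / mean_snps)
  }
  if (is.null(coverage)) coverage <- round(n_reads * mean_snps / l, 2)
  set.seed(seed)
  n_cells <- length(n_reads) * length(error_rates) * length(solvers)
  seed_pool <- matrix(sample.int(.Machine$integer.max - 1L, n_cells * trials),
                      nrow = trials)
  rows <- list(); cell <- 0L
  for (ci in seq_along(n_reads)) {
    for (e in error_rates) {
      for (sv in solvers) {
        cell <- cell + 1L
        res <- matrix(NA_real_, trials, 2)
        failed <- 0L
        for (t in seq_len(trials)) {
          out <- tryCatch(
            .benchmark_trial(l, n_reads[ci], e, sv, rank, all_het,
                             mean_snps, gap_mean, seed_pool[t, cell]),
            error = function(err) NULL)
          if (is.null(out)) failed <- failed + 1L else res[t, ] <- out
        }
        ok <- stats::complete.cases(res)
        se <- function(v) stats::sd(v) / sqrt(length(v))
        rows[[cell]] <- data.frame(
          n_reads = n_reads[ci], coverage = coverage[ci], error_rate = e,
          solver = sv,
          mean_rr = mean(res[ok, 1]), se_rr = se(res[ok, 1]),
          mean_swer = mean(res[ok, 2]), se_swer = se(res[ok, 2]),
          trials_ok = sum(ok), trials_failed = failed)
      }
    }
  }
  do.call(rbind, rows)
}
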