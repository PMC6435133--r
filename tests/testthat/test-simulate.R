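test_that("simulated truth pairs honour the heterozygosity model", {
  p <- simulate_truth(10, seed = 1)
  expect_length(p$h1, 10)
  expect_true(all(p$h1 * p$h2 == -1))          # all-het: negatives
  expect_true(pair_identical(simulate_truth(10, seed = 1), p,
                             allow_swap = FALSE))
  q <- simulate_truth(2000, all_het = FALSE, het_fraction = 0.3, seed = 2)
  frac <- mean(q$h1 != q$h2)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
})

test_that("simulated reads have the prescribed footprint statistics", {
  truth <- simulate_truth(700, seed = 3)
  frags <- simulate_reads(truth, coverage = 3, seed = 3)
  expect_length(frags, round(3 * 700 / 7.4))
  sizes <- vapply(frags, function(f) length(f$sites), numeric(1))
  expect_true(all(sizes >= 2))
  expect_lt(abs(mean(sizes) - 7.4), 0.2)
  sites <- unlist(lapply(frags, `[[`, "sites"))
  expect_true(all(sites >= 1 & sites <= 700))
  # per-column coverage concentrates around c
  cov <- tabulate(sites, nbins = 700)
  expect_lt(abs(mean(cov) - 3) / 3, 0.1)
  # reproducibility
  frags2 <- simulate_reads(truth, coverage = 3, seed = 3)
  expect_identical(frags2, frags)
  # observations copy one parent exactly when error-free
  for (f in frags[1:20]) {
    match1 <- all(f$alleles == truth$h1[f$sites])
    match2 <- all(f$alleles == truth$h2[f$sites])
    expect_true(match1 || match2)
  }
})

test_that("noise contamination flips the expected fraction of cells", {
  truth <- simulate_truth(200, seed = 4)
  frags <- simulate_reads(truth, coverage = 25, mean_snps = 5, seed = 4)
  rm <- build_read_matrix(frags, 200)
  n <- n_observed(rm)
  expect_gte(n, 5000)
  expect_identical(as_dense(add_read_noise(rm, 0, seed = 1)), as_dense(rm))
  # literal flip model: fraction ~ e
  noisy <- add_read_noise(rm, 0.1, model = "flip", seed = 5)
  flipped <- sum(as_dense(noisy) != as_dense(rm))
  expect_lt(abs(flipped / n - 0.1), 3 * sqrt(0.1 * 0.9 / n))
  # uniform contamination: e of the cells contaminated, half of them flip
  unif <- add_read_noise(rm, 0.2, model = "uniform", seed = 6)
  flipped_u <- sum(as_dense(unif) != as_dense(rm))
  expect_lt(abs(flipped_u / n - 0.1), 3 * sqrt(0.1 * 0.9 / n))
  # flipping twice with the same seed restores the original
  twice <- add_read_noise(noisy, 0.1, model = "flip", seed = 5)
  expect_identical(as_dense(twice), as_dense(rm))
  # Omega is never changed
  expect_identical(observed_cells(noisy)[, 1:2], observed_cells(rm)[, 1:2])
})

test_that("benchmark runs are deterministic and exact when noiseless", {
  # coverage high enough that every column is observed in every trial
  tab <- run_benchmark(l = 120, coverage = 10, error_rates = 0,
                       trials = 3, seed = 11)
  expect_equal(tab$mean_rr, 1)
  expect_equal(tab$mean_swer, 0)
  tab2 <- run_benchmark(l = 120, coverage = 10, error_rates = 0,
                        trials = 3, seed = 11)
  expect_identical(tab, tab2)
  expect_equal(tab$trials_failed, 0L)
})

test_that("benchmark accuracy responds to coverage and noise as expected", {
  tab <- run_benchmark(l = 150, n_reads = c(60L, 200L),
                       error_rates = c(0.1, 0.3), trials = 4, seed = 21)
  ord <- function(n, e) which(tab$n_reads == n & tab$error_rate == e)
  # more noise never helps, more coverage never hurts (within 2 se)
  expect_gte(tab$mean_rr[ord(60, 0.1)] + 2 * tab$se_rr[ord(60, 0.1)],
             tab$mean_rr[ord(60, 0.3)] - 2 * tab$se_rr[ord(60, 0.3)])
  expect_gte(tab$mean_rr[ord(200, 0.1)] + 2 * tab$se_rr[ord(200, 0.1)],
             tab$mean_rr[ord(60, 0.1)] - 2 * tab$se_rr[ord(60, 0.1)])
})
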