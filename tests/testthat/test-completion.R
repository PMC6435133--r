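test_that("singular value shrinkage soft-thresholds the spectrum", {
  expect_equal(shrink_singular_values(diag(c(3, 1)), 2), diag(c(1, 0)))
  set.seed(1)
  M <- matrix(rnorm(20), 4, 5)
  expect_equal(shrink_singular_values(M, 0), M, tolerance = 1e-10)
  u <- rnorm(4); v <- rnorm(5)
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  expect_equal(shrink_singular_values(5 * u %*% t(v), 5),
               matrix(0, 4, 5), tolerance = 1e-9)
  # spectrum of the output is exactly max(sigma - tau, 0)
  for (k in 1:5) {
    M <- matrix(rnorm(35), 5, 7)
    tau <- runif(1, 0, 3)
    expect_equal(svd(shrink_singular_values(M, tau))$d,
                 pmax(svd(M)$d - tau, 0), tolerance = 1e-9)
  }
})

test_that("shrinkage minimizes the proximal nuclear-norm objective", {
  # brute-force candidate check on 3x3 instances: no perturbation of the
  # output, nor any random candidate, attains a lower objective
  objective <- function(M, Z, tau) 0.5 * sum((M - Z)^2) + tau * sum(svd(Z)$d)
  set.seed(2)
  for (k in 1:10) {
    M <- matrix(rnorm(9), 3, 3)
    tau <- runif(1, 0.1, 2)
    Z0 <- shrink_singular_values(M, tau)
    f0 <- objective(M, Z0, tau)
    for (j in 1:40) {
      Z <- Z0 + matrix(rnorm(9, sd = sample(c(0.01, 0.1, 1), 1)), 3, 3)
      expect_gte(objective(M, Z, tau), f0 - 1e-9)
    }
  }
})

test_that("SVT completes the worked example to its observed entries", {
  rm <- b2ar_read_matrix()
  H <- suppressWarnings(complete_svt(rm, max_iter = 6000L))
  d <- attr(H, "diagnostics")
  expect_true(d$converged)
  # last trace value satisfies the stopping rule
  expect_lte(d$residual, 1e-4)
  expect_equal(d$residual, d$residual_trace[length(d$residual_trace)])
  obs <- observed_cells(rm)
  expect_lte(sqrt(sum((H[cbind(obs$i, obs$j)] - obs$x)^2)),
             1e-4 * sqrt(45))
  # cells determined by the rank-2 model agree with the
  # parent-haplotype completion (reads 2 and 9 observe only sites where
  # the haplotypes are opposite, so their values at the two agreeing
  # sites are under-determined and excluded here)
  G <- b2ar_completed()
  mask <- matrix(TRUE, 10, 10)
  mask[rbind(c(2, 2), c(2, 10), c(9, 2), c(9, 10))] <- FALSE
  expect_identical(sign(H)[mask], G[mask])
})

test_that("SVT handles the fully observed and empty cases", {
  G <- b2ar_completed()
  H <- suppressWarnings(complete_svt(read_matrix(G), max_iter = 6000L))
  expect_lte(attr(H, "diagnostics")$residual, 1e-4)
  expect_error(complete_svt(build_read_matrix(list(), 5)), "no observed")
  # non-convergence is flagged, not an error
  expect_warning(Hs <- complete_svt(b2ar_read_matrix(), max_iter = 3L),
                 "did not reach")
  expect_false(attr(Hs, "diagnostics")$converged)
})

test_that("nuclear-norm completion satisfies its constraint and edge cases", {
  rm <- b2ar_read_matrix()
  H <- suppressWarnings(complete_nuclear(rm, max_iter = 4000L))
  obs <- observed_cells(rm)
  eps <- attr(H, "diagnostics")$eps
  expect_lte(sqrt(sum((H[cbind(obs$i, obs$j)] - obs$x)^2)), eps * (1 + 1e-6))
  # determined cells match the parent completion
  G <- b2ar_completed()
  mask <- matrix(TRUE, 10, 10)
  mask[rbind(c(2, 2), c(2, 10), c(9, 2), c(9, 10))] <- FALSE
  expect_identical(sign(H)[mask], G[mask])
  # eps >= ||R||_F makes the zero matrix optimal
  H0 <- complete_nuclear(rm, eps = sqrt(45) * 1.01)
  expect_lte(max(abs(H0)), 1e-4)
  # fully observed: the returned point stays within eps of R everywhere
  Hf <- complete_nuclear(read_matrix(G))
  expect_lte(sqrt(sum((Hf - G)^2)), attr(Hf, "diagnostics")$eps * (1 + 1e-6))
  expect_lte(sum(svd(Hf)$d), sum(svd(G)$d) + 1e-6)
  expect_error(complete_nuclear(rm, size_cap = 10), "size cap")
})

test_that("trimming zeroes only over-observed rows and columns", {
  rm <- b2ar_read_matrix()
  tr <- trim_overobserved(rm)          # thresholds 2*45/10 = 9
  expect_identical(as_dense(tr), as_dense(rm))
  expect_length(attr(tr, "trimmed_cols"), 0)
  # a column observed by all 10 reads while 2|Omega|/l = 4 gets zeroed
  M <- matrix(0, 10, 10)
  M[, 1] <- 1
  M[cbind(1:10, 2 + (0:9) %% 5)] <- 1       # |Omega| = 20, col thr = 4
  tr2 <- trim_overobserved(read_matrix(M))
  expect_equal(attr(tr2, "trimmed_cols"), 1L)
  expect_true(all(as_dense(tr2)[, 1] == 0))
  expect_length(attr(tr2, "trimmed_rows"), 0)
  # uniform-degree matrices are never trimmed
  rm3 <- read_matrix(matrix(1, 6, 6))
  expect_identical(as_dense(trim_overobserved(rm3)), as_dense(rm3))
})

test_that("rank-r projection rescales the truncated SVD", {
  # rank-1 fully observed: projection reproduces the matrix exactly
  u <- c(1, -1, 1); v <- c(1, 1, -1, -1)
  M <- u %*% t(v)
  p1 <- project_rank_r(read_matrix(M), 1)
  expect_equal(p1$X %*% p1$S %*% t(p1$Y), M, tolerance = 1e-9,
               ignore_attr = TRUE)
  # worked example, r = 2: top-2 SVD scaled by N*l/|Omega| = 100/45
  rm <- b2ar_read_matrix()
  p2 <- project_rank_r(rm, 2)
  s <- svd(as_dense(rm))
  expect_equal(abs(diag(p2$S)), s$d[1:2] * 100 / 45, tolerance = 1e-8)
  recon <- p2$X %*% p2$S %*% t(p2$Y)
  direct <- (100 / 45) * s$u[, 1:2] %*% diag(s$d[1:2]) %*% t(s$v[, 1:2])
  expect_equal(recon, direct, tolerance = 1e-8, ignore_attr = TRUE)
  # r above the matrix rank flags padding with orthonormal factors
  p3 <- project_rank_r(read_matrix(M), 3)
  expect_true(p3$padded)
  expect_equal(crossprod(p3$X), diag(3), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("internal SVD backends agree", {
  set.seed(33)
  M <- matrix(sample(c(-1, 0, 0, 1), 600 * 80, replace = TRUE), 600, 80)
  full <- svd(M)
  fast <- matrixphase:::.svd_auto(M, size_switch = 10)
  expect_equal(fast$d[1:5], full$d[1:5], tolerance = 1e-8)
  expect_equal(abs(diag(crossprod(fast$u[, 1:5], full$u[, 1:5]))),
               rep(1, 5), tolerance = 1e-6)
})

test_that("OPTSPACE cleaning descends monotonically and fits exactly", {
  rm <- b2ar_read_matrix()
  init <- project_rank_r(trim_overobserved(rm), 2)
  H <- optspace_clean(rm, init, max_iter = 500L, tol = 1e-10)
  d <- attr(H, "diagnostics")
  expect_true(all(diff(d$objective_trace) <= 0))
  expect_lte(d$objective, 1e-6)
  obs <- observed_cells(rm)
  expect_equal(H[cbind(obs$i, obs$j)], obs$x, tolerance = 1e-4)
  # an already-optimal initialization converges immediately
  G <- b2ar_completed()
  s <- svd(G)
  exact <- structure(list(X = s$u[, 1:2], S = diag(s$d[1:2]),
                          Y = s$v[, 1:2], r = 2L, padded = FALSE),
                     class = "factor_triple")
  H2 <- optspace_clean(read_matrix(G), exact, max_iter = 100L)
  expect_lte(attr(H2, "diagnostics")$iterations, 2L)
  expect_lte(attr(H2, "diagnostics")$objective, 1e-12)
})

test_that("the full OPTSPACE chain recovers structured instances", {
  rm <- b2ar_read_matrix()
  H <- complete_optspace(rm, r = 2)
  # exact rank 2 by construction
  expect_lte(svd(H)$d[3], 1e-6 * svd(H)$d[1])
  expect_error(complete_optspace(rm, r = 3), "rank must be 1 or 2")
  # all-heterozygous noiseless instance, r = 1: exact recovery
  set.seed(9)
  truth <- simulate_truth(40, all_het = TRUE)
  frags <- simulate_reads(truth, n_reads = 40L, mean_snps = 4, gap_mean = 8)
  rm1 <- build_read_matrix(frags, 40)
  H1 <- complete_optspace(rm1, r = 1)
  est <- extract_haplotypes(H1, rank = 1)
  expect_equal(reconstruction_rate(est, truth), 1)
})
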