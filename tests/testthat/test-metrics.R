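test_that("augmented Hamming distance treats missing as mismatch", {
  expect_equal(hamming_distance(b2ar_hm, b2ar_hm), 0)
  expect_equal(hamming_distance(b2ar_hm, b2ar_hp), 8)   # 2 agreeing sites
  expect_equal(hamming_distance(c(1, 1, NA), c(1, -1, 1)), 2)
  expect_equal(hamming_distance(c(NA, NA), c(NA, 1)), 1)
  expect_error(hamming_distance(1, c(1, 1)), "equal length")
})

test_that("reconstruction rate is label-swap invariant", {
  truth <- b2ar_truth()
  expect_equal(reconstruction_rate(truth, truth), 1)
  swapped <- haplotype_pair(truth$h2, truth$h1)
  expect_equal(reconstruction_rate(swapped, truth), 1)
  # one error on each strand: the better strand still carries one
  est <- haplotype_pair(replace(truth$h1, 3, -truth$h1[3]),
                        replace(truth$h2, 5, -truth$h2[5]))
  expect_equal(reconstruction_rate(est, truth), 0.9)
  # an error on only one strand leaves the better strand perfect
  est1 <- haplotype_pair(replace(truth$h1, 3, -truth$h1[3]), truth$h2)
  expect_equal(reconstruction_rate(est1, truth), 1)
})

test_that("per-block reconstruction aligns labels within each block", {
  truth <- haplotype_pair(rep(1, 10), rep(-1, 10))
  # second block phased with flipped labels: globally imperfect,
  # per-block perfect
  est <- haplotype_pair(c(rep(1, 5), rep(-1, 5)), c(rep(-1, 5), rep(1, 5)))
  blocks <- list(1:5, 6:10)
  expect_equal(reconstruction_rate(est, truth, blocks), 1)
  expect_lt(reconstruction_rate(est, truth), 1)
  # sites in no block count as errors
  est2 <- haplotype_pair(c(rep(1, 8), NA, NA), c(rep(-1, 8), NA, NA))
  expect_equal(reconstruction_rate(est2, truth, list(1:8)), 0.8)
})

test_that("the four-SNP switch example yields one long switch", {
  truth <- haplotype_pair(c(1, 1, 1, 1), c(-1, -1, -1, -1))
  est <- haplotype_pair(c(1, 1, -1, -1), c(-1, -1, 1, 1))
  sw <- count_switches(est, truth)
  expect_equal(sw$count, 1L)
  expect_equal(sw$positions, 3L)
  expect_equal(switch_error_rate(est, truth), 0.25)
  cls <- classify_switches(est, truth)
  expect_equal(cls, list(short = 0L, long = 1L))
})

test_that("a point mismatch is two switches classified as one short", {
  truth <- haplotype_pair(c(1, 1, 1, 1), c(-1, -1, -1, -1))
  est <- haplotype_pair(c(1, -1, 1, 1), c(-1, 1, -1, -1))
  expect_equal(count_switches(est, truth)$count, 2L)
  expect_equal(classify_switches(est, truth), list(short = 1L, long = 0L))
  expect_equal(count_switches(truth, truth)$count, 0L)
  expect_equal(classify_switches(truth, truth), list(short = 0L, long = 0L))
})

test_that("switch accounting skips homozygous and missing sites", {
  # truth homozygous at site 3: no switch can occur across it
  truth <- haplotype_pair(c(1, 1, 1, 1, 1), c(-1, -1, 1, -1, -1))
  est <- haplotype_pair(c(1, 1, 1, 1, 1), c(-1, -1, -1, -1, -1))
  expect_equal(count_switches(est, truth)$count, 0L)
  # missing estimate sites are skipped, not counted
  est2 <- haplotype_pair(c(1, NA, 1, NA, 1), c(-1, NA, 1, NA, -1))
  expect_equal(count_switches(est2, truth)$count, 0L)
})

test_that("switch metrics are invariant to a global label flip", {
  set.seed(8)
  truth <- simulate_truth(60)
  e1 <- ifelse(runif(60) < 0.12, -truth$h1, truth$h1)
  est <- haplotype_pair(e1, -e1)
  flip <- haplotype_pair(-e1, e1)
  expect_equal(count_switches(flip, truth)$count,
               count_switches(est, truth)$count)
  expect_equal(classify_switches(flip, truth), classify_switches(est, truth))
  # classified events = flipped runs relative to the dominant label
  cls <- classify_switches(est, truth)
  lab <- ifelse(e1 == truth$h1, 1L, -1L)
  runs <- rle(lab)
  tab <- table(factor(lab, c(-1, 1)))
  ref <- if (tab[1] == tab[2]) lab[1] else c(-1L, 1L)[which.max(tab)]
  expect_equal(cls$short + cls$long, sum(runs$values != ref))
})

test_that("SWER times haplotype length equals the switch count", {
  set.seed(12)
  truth <- simulate_truth(50)
  e1 <- ifelse(runif(50) < 0.1, -truth$h1, truth$h1)
  est <- haplotype_pair(e1, -e1)
  sw <- count_switches(est, truth)
  expect_equal(switch_error_rate(est, truth) * 50, sw$count)
})

test_that("SNP missing rate counts fully unphased sites", {
  est <- haplotype_pair(c(1, -1, NA, 1), c(-1, 1, NA, -1))
  expect_equal(snp_missing_rate(est), 0.25)
  expect_equal(snp_missing_rate(b2ar_truth()), 0)
  expect_equal(snp_missing_rate(haplotype_pair(rep(NA_real_, 5),
                                               rep(NA_real_, 5))), 1)
  # smr + phased fraction = 1 for complete call sets
  full <- haplotype_pair(c(1, -1, 1), c(-1, 1, -1))
  expect_equal(snp_missing_rate(full) +
                 mean(!is.na(full$h1) & !is.na(full$h2)), 1)
})

test_that("block statistics implement the adjusted N50", {
  expect_equal(block_stats(1000, 1), list(mean_span = 1000, an50 = 1000))
  # two equal blocks, one fully and one half correct
  expect_equal(block_stats(c(1000, 1000), c(1, 0.5))$an50, 1000)
  expect_equal(block_stats(c(1000, 1000), c(1, 0.5))$mean_span, 1000)
  expect_equal(block_stats(10, 1)$mean_span, 10)   # SNP-count mode
  expect_true(is.na(block_stats(numeric(0))$mean_span))
  # running sum that never reaches half the raw total
  expect_true(is.na(block_stats(c(100, 100), c(0.1, 0.1))$an50))
})
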