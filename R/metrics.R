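#' Augmented Hamming distance
#'
#' Counts positions where two allele vectors differ.  A missing value
#' (`NA`) is unequal to +1 or -1, and two missing values are equal: the
#' distance is literal positionwise disagreement.
#'
#' @param a,b numeric vectors of equal length over \{+1, -1, NA\}
#' @return integer count of disagreeing positions
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  same <- (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
  sum(!same)
}

# swap est labels if that lowers total distance to truth
.align_labels <- function(est, truth) {
  d_keep <- hamming_distance(est$h1, truth$h1) + hamming_distance(est$h2, truth$h2)
  d_swap <- hamming_distance(est$h1, truth$h2) + hamming_distance(est$h2, truth$h1)
  if (d_swap < d_keep) haplotype_pair(est$h2, est$h1, est$ambiguous) else est
}

#' Reconstruction rate
#'
#' `rr = 1 - min(HD(est_m, truth_m), HD(est_p, truth_p)) / l`, after the
#' interchangeable labels of the estimate are assigned to the truth by
#' total-distance minimization.  `rr = 1` iff the better-matched strand is
#' error-free at every site; unphased sites count as errors.
#'
#' When the estimate was phased in independent haplotype blocks the label
#' of every block is arbitrary, so with `blocks` given the assignment is
#' made per block (the interchangeability applied at the unit of
#' independent phasing); per-strand distances are then accumulated over
#' blocks, sites outside every block count as errors on both strands, and
#' the same `1 - min(.)/l` rule is applied to the totals.
#'
#' @param est,truth [haplotype_pair] objects of equal length
#' @param blocks optional list of per-block SNP index vectors
#' @return reconstruction rate in `[0, 1]`
#' @export
reconstruction_rate <- function(est, truth, blocks = NULL) {
  l <- length(truth$h1)
  if (length(est$h1) != l) stop("estimate and truth lengths differ")
  if (is.null(blocks)) {
    est <- .align_labels(est, truth)
    return(1 - min(hamming_distance(est$h1, truth$h1),
                   hamming_distance(est$h2, truth$h2)) / l)
  }
  hd1 <- 0L; hd2 <- 0L
  for (sites in blocks) {
    sub_est <- haplotype_pair(est$h1[sites], est$h2[sites])
    sub_tru <- haplotype_pair(truth$h1[sites], truth$h2[sites])
    sub_est <- .align_labels(sub_est, sub_tru)
    hd1 <- hd1 + hamming_distance(sub_est$h1, sub_tru$h1)
    hd2 <- hd2 + hamming_distance(sub_est$h2, sub_tru$h2)
  }
  outside <- setdiff(seq_len(l), unlist(blocks))
  hd1 <- hd1 + length(outside); hd2 <- hd2 + length(outside)
  1 - min(hd1, hd2) / l
}

# parental-agreement labels over consecutive phased heterozygous sites:
# +1 where est h1 tracks truth h1, -1 where it tracks truth h2
.agreement_labels <- function(est, truth, sites = NULL) {
  l <- length(truth$h1)
  if (is.null(sites)) sites <- seq_len(l)
  het <- !is.na(truth$h1) & !is.na(truth$h2) & truth$h1 != truth$h2
  phased <- !is.na(est$h1)
  use <- intersect(sites, which(het & phased))
  use <- use[order(use)]
  list(pos = use,
       label = ifelse(est$h1[use] == truth$h1[use], 1L, -1L))
}

#' Count phase switches against a truth pair
#'
#' A switch occurs between two consecutive compared SNPs when the parental
#' origin the estimate tracks changes.  Comparison runs over consecutive
#' heterozygous truth sites at which the estimate is phased; homozygous
#' truth sites are excluded (parental origin is undefined there) and
#' missing estimate sites are skipped.  When `blocks` is given, labels are
#' restarted at each block boundary (phase across blocks is arbitrary)
#' and counts are summed.
#'
#' @param est,truth [haplotype_pair] objects of equal length
#' @param blocks optional list of per-block SNP index vectors
#' @return list with `count` and `positions` (index of the right-hand SNP
#'   of each switch)
#' @export
count_switches <- function(est, truth, blocks = NULL) {
  if (is.null(blocks)) blocks <- list(seq_along(truth$h1))
  count <- 0L; positions <- integer(0)
  for (sites in blocks) {
    al <- .agreement_labels(est, truth, sites)
    if (length(al$label) < 2L) next
    ch <- which(diff(al$label) != 0L)
    count <- count + length(ch)
    positions <- c(positions, al$pos[ch + 1L])
  }
  list(count = count, positions = positions)
}

#' Classify switch events as short or long
#'
#' Within each block the agreement-label sequence is reduced to runs
#' relative to the dominant label (majority; ties go to the first run's
#' label).  Each flipped run is one classified event: a run of length 1
#' (an isolated point mismatch -- the back-to-back switch pair) is a
#' *short* switch; a run of length >= 2 (the tracked parent stays flipped
#' for at least two SNPs) is a *long* switch.
#'
#' @param est,truth [haplotype_pair] objects of equal length
#' @param blocks optional list of per-block SNP index vectors
#' @return list with `short` and `long` event counts
#' @export
classify_switches <- function(est, truth, blocks = NULL) {
  if (is.null(blocks)) blocks <- list(seq_along(truth$h1))
  short <- 0L; long <- 0L
  for (sites in blocks) {
    al <- .agreement_labels(est, truth, sites)
    if (length(al$label) < 2L) next
    tab <- table(al$label)
    ref <- if (length(tab) == 1L || tab[1] != tab[2]) {
      as.integer(names(tab)[which.max(tab)])
    } else {
      al$label[1]
    }
    r <- rle(al$label)
    flipped <- r$values != ref
    short <- short + sum(flipped & r$lengths == 1L)
    long <- long + sum(flipped & r$lengths >= 2L)
  }
  list(short = short, long = long)
}

#' Switch error rate
#'
#' Number of switches divided by the haplotype length `l`.
#'
#' @param est,truth [haplotype_pair] objects of equal length
#' @param blocks optional list of per-block SNP index vectors
#' @param l haplotype length; defaults to the truth length
#' @return switches per SNP
#' @export
switch_error_rate <- function(est, truth, blocks = NULL, l = NULL) {
  if (is.null(l)) l <- length(truth$h1)
  count_switches(est, truth, blocks)$count / l
}

#' SNP missing rate
#'
#' Fraction of the `l` SNPs left unphased by the assembler: sites with
#' missing calls in both estimated haplotypes, including SNPs in no
#' block.
#'
#' @param est a [haplotype_pair] of full length `l` (blockless SNPs NA)
#' @param l haplotype length; defaults to the estimate length
#' @return rate in `[0, 1]`
#' @export
snp_missing_rate <- function(est, l = NULL) {
  if (is.null(l)) l <- length(est$h1)
  stopifnot(l > 0)
  sum(is.na(est$h1) & is.na(est$h2)) / l
}

#' Block length statistics: mean span and adjusted N50 (AN50)
#'
#' Each block's span is weighted by the fraction of its alleles phased
#' correctly, giving an adjusted span.  Blocks are sorted by adjusted span
#' (descending); the AN50 is the adjusted span of the block at which the
#' running sum of adjusted spans first reaches half the total unadjusted
#' span.  If the running sum never reaches halfway (possible when
#' correctness fractions are low), `an50` is `NA`.
#'
#' @param spans numeric vector of block spans (bp from a site map, or SNP
#'   counts -- state which in reporting)
#' @param correct_fraction per-block fraction of correctly phased alleles
#'   (default all 1)
#' @return list with `mean_span` and `an50`; both `NA` when there are no
#'   blocks
#' @export
block_stats <- function(spans, correct_fraction = rep(1, length(spans))) {
  if (!length(spans)) return(list(mean_span = NA_real_, an50 = NA_real_))
  stopifnot(length(correct_fraction) == length(spans),
            all(correct_fraction >= 0 & correct_fraction <= 1))
  adj <- spans * correct_fraction
  ord <- order(adj, decreasing = TRUE)
  cum <- cumsum(adj[ord])
  half <- sum(spans) / 2
  k <- which(cum >= half)[1]
  list(mean_span = mean(spans),
       an50 = if (is.na(k)) NA_real_ else adj[ord][k])
}

#' Per-block correctness fractions against a truth pair
#'
#' For each block, the fraction of its (site, haplotype) allele calls that
#' match the truth under the block's best label assignment.
#'
#' @param est,truth [haplotype_pair] objects of equal length
#' @param blocks list of per-block SNP index vectors
#' @return numeric vector, one fraction per block
#' @export
block_correctness <- function(est, truth, blocks) {
  vapply(blocks, function(sites) {
    sub_est <- haplotype_pair(est$h1[sites], est$h2[sites])
    sub_tru <- haplotype_pair(truth$h1[sites], truth$h2[sites])
    sub_est <- .align_labels(sub_est, sub_tru)
    n <- 2L * length(sites)
    (n - hamming_distance(sub_est$h1, sub_tru$h1) -
        hamming_distance(sub_est$h2, sub_tru$h2)) / n
  }, numeric(1))
}
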