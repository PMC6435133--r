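#' Haplotype pair container
#'
#' Two length-`l` vectors over \{+1, -1, NA\} (NA = unphased/missing).
#' The two labels are interchangeable: no assembly method can tell the
#' maternal from the paternal haplotype, so downstream comparisons treat
#' the pair as unordered (`ambiguous = TRUE`).
#'
#' @param h1,h2 numeric vectors of equal length over \{+1, -1, NA\}
#' @param ambiguous whether the labels carry no maternal/paternal meaning
#' @return list of class `haplotype_pair`
#' @export
haplotype_pair <- function(h1, h2, ambiguous = TRUE) {
  stopifnot(length(h1) == length(h2))
  ok <- function(v) all(is.na(v) | v %in% c(-1, 1))
  if (!ok(h1) || !ok(h2))
    stop("haplotype entries must be +1, -1 or NA")
  structure(list(h1 = as.numeric(h1), h2 = as.numeric(h2),
                 ambiguous = isTRUE(ambiguous)),
            class = "haplotype_pair")
}

#' @export
print.haplotype_pair <- function(x, ...) {
  fmt <- function(v) paste(ifelse(is.na(v), "-", ifelse(v > 0, "+", "−")),
                           collapse = "")
  cat(sprintf("<haplotype_pair> l = %d%s\n  h1: %s\n  h2: %s\n",
              length(x$h1), if (x$ambiguous) " (labels interchangeable)" else "",
              fmt(x$h1), fmt(x$h2)))
  invisible(x)
}

#' Compare two haplotype pairs as unordered sets
#'
#' @param a,b [haplotype_pair] objects of equal length
#' @param allow_swap also accept equality after swapping b's labels
#' @return TRUE if the pairs are elementwise identical (NA matching NA),
#'   directly or (if allowed) after a label swap
#' @export
pair_identical <- function(a, b, allow_swap = TRUE) {
  same <- function(u, v) length(u) == length(v) &&
    all((is.na(u) & is.na(v)) | (!is.na(u) & !is.na(v) & u == v))
  (same(a$h1, b$h1) && same(a$h2, b$h2)) ||
    (allow_swap && same(a$h1, b$h2) && same(a$h2, b$h1))
}

#' Select pivot rows of a completed matrix
#'
#' The reduced row echelon form of `H^T` is computed (with a pivot
#' tolerance relative to the largest entry of `H`); its first two pivot
#' positions are the indices of the first two linearly independent rows
#' of `H` -- the representatives of the two haplotypes.  Implemented as a
#' rank-revealing sweep (incremental orthogonalization), which selects
#' exactly the RREF pivot columns: a column of `H^T` is a pivot iff it is
#' independent of the columns before it.
#'
#' @param H numeric matrix (a completed read matrix), nonzero
#' @param tol pivot tolerance relative to `max(abs(H))`.  The default
#'   (1e-2) sits above the convergence tolerances of the completion
#'   solvers (whose iterates carry residuals up to about 1e-3 of the
#'   matrix scale) and two orders of magnitude below the O(1) residual
#'   of a genuinely independent haplotype row; a tolerance below the
#'   solver accuracy would declare numerically identical rows
#'   independent.
#' @return integer vector `c(p1, p2)`; `p2` is `NA` when the numerical
#'   rank is 1
#' @export
select_pivot_rows <- function(H, tol = 1e-2) {
  H <- as.matrix(H)
  scale <- max(abs(H))
  if (scale == 0) stop("cannot select pivots of an all-zero matrix")
  thr <- tol * scale
  B <- NULL
  pivots <- integer(0)
  for (i in seq_len(nrow(H))) {
    v <- H[i, ]
    if (!is.null(B)) v <- v - B %*% crossprod(B, v)
    if (max(abs(v)) > thr) {
      B <- cbind(B, v / sqrt(sum(v^2)))
      pivots <- c(pivots, i)
      if (length(pivots) == 2L) break
    }
  }
  if (!length(pivots)) stop("cannot select pivots of an all-zero matrix")
  c(pivots[1], if (length(pivots) > 1L) pivots[2] else NA_integer_)
}

#' Quantize a completed matrix to signs
#'
#' Entries above `zero_band` become +1, below `-zero_band` become -1, and
#' entries within the band (including exact zeros) become `NA` (missing).
#' With `zero_band = 0` this is the hard sign rule except that exact zeros
#' -- cells the completion left undetermined, e.g. whole unobserved
#' columns -- are reported missing rather than forced to an allele.
#'
#' @param H numeric matrix
#' @param zero_band half-width of the missing band, `>= 0`
#' @return matrix over \{+1, -1, NA\}
#' @export
quantize_signs <- function(H, zero_band = 0) {
  stopifnot(zero_band >= 0)
  out <- ifelse(H > zero_band, 1, ifelse(H < -zero_band, -1, NA_real_))
  dim(out) <- dim(H)
  out
}

#' Extract the haplotype pair from a completed matrix
#'
#' The completed matrix is quantized to signs and the two pivot rows
#' (from [select_pivot_rows()] on the unquantized matrix) are taken as
#' the haplotype representatives.  Under `rank = 1`, or when only one
#' pivot exists, the second haplotype is the negative of the first
#' (all-heterozygous model), with missing staying missing.
#'
#' The pivot-row rule is exact on a noiseless low-rank completion but
#' fragile under noise: the first rows to look linearly independent are
#' often precisely the reads carrying errors.  The optional consensus
#' mode (`consensus = TRUE`, off by default to keep the plain pivot-row
#' rule) therefore re-estimates each haplotype as the majority sign over
#' all rows clustered to its pivot (each row is assigned, with a free
#' orientation sign, to the pivot it agrees with best), out-voting
#' isolated read errors.
#'
#' @param H completed matrix
#' @param rank 1 or 2
#' @param zero_band passed to [quantize_signs()]
#' @param tol pivot tolerance for [select_pivot_rows()]
#' @param consensus use cluster-majority refinement (see above)
#' @return a [haplotype_pair] (labels ambiguous); attribute `"pivots"`
#'   records the selected rows
#' @export
extract_haplotypes <- function(H, rank = 2L, zero_band = 0, tol = 1e-2,
                               consensus = FALSE) {
  stopifnot(rank %in% c(1L, 2L))
  p <- select_pivot_rows(H, tol = tol)
  Hq <- quantize_signs(H, zero_band = zero_band)
  h1 <- Hq[p[1], ]
  if (rank == 1L || is.na(p[2])) {
    h2 <- -h1
  } else {
    h2 <- Hq[p[2], ]
  }
  if (consensus) {
    piv <- rbind(ifelse(is.na(h1), 0, h1), ifelse(is.na(h2), 0, h2))
    scores <- Hq
    scores[is.na(scores)] <- 0
    A <- scores %*% t(piv)                  # row-vs-pivot agreement
    if (rank == 1L || is.na(p[2])) {
      # one haplotype up to sign: cluster with a free orientation
      k <- max.col(abs(A), ties.method = "first")
      sgn <- sign(A[cbind(seq_len(nrow(A)), k)])
      sgn[sgn == 0] <- 1
    } else {
      # two distinct haplotypes: rows keep their orientation
      k <- max.col(A, ties.method = "first")
      sgn <- rep(1, nrow(A))
    }
    for (cl in 1:2) {
      member <- which(k == cl)
      if (!length(member)) next
      tallied <- colSums(scores[member, , drop = FALSE] * sgn[member])
      cons <- ifelse(tallied > 0, 1, ifelse(tallied < 0, -1, NA_real_))
      if (rank == 1L || is.na(p[2])) {
        h1 <- if (cl == 1L) cons else h1
        h2 <- -h1
        break
      } else if (cl == 1L) h1 <- cons else h2 <- cons
    }
  }
  out <- haplotype_pair(h1, h2, ambiguous = TRUE)
  attr(out, "pivots") <- p
  out
}
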