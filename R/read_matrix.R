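#' Sparse read matrix container
#'
#' The central data structure of the package: an `N x l` sparse matrix with
#' one row per sequencing read and one column per SNP site.  Stored entries
#' are +1 (read carries the wild allele) or -1 (rare allele); structural
#' zeros are unobserved cells.  The observed-index set Omega is exactly the
#' nonzero pattern.
#'
#' @param mat a base matrix or [Matrix::Matrix] with entries in \{-1, 0, +1\};
#'   zeros are treated as unobserved.
#' @return an object of class `read_matrix`: a list with elements `mat`
#'   (a `dgCMatrix`), `n_reads` and `n_sites`.
#' @examples
#' rm <- read_matrix(rbind(c(1, -1, 0), c(0, -1, 1)))
#' n_observed(rm)
#' @export
read_matrix <- function(mat) {
  m <- Matrix::Matrix(mat, sparse = TRUE)
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  m <- Matrix::drop0(m * 1)
  if (length(m@x) && !all(m@x %in% c(-1, 1)))
    stop("read matrix entries must be -1, 0 (unobserved) or +1")
  structure(list(mat = m, n_reads = nrow(m), n_sites = ncol(m)),
            class = "read_matrix")
}

#' @export
print.read_matrix <- function(x, ...) {
  cat(sprintf("<read_matrix> %d reads x %d SNP sites, %d observed cells\n",
              x$n_reads, x$n_sites, n_observed(x)))
  invisible(x)
}

#' Number of observed cells |Omega|
#' @param rm a [read_matrix]
#' @return integer count of observed (nonzero) cells
#' @export
n_observed <- function(rm) length(rm$mat@x)

#' Observed cells of a read matrix
#'
#' @param rm a [read_matrix]
#' @return a data frame with columns `i` (read row), `j` (SNP column) and
#'   `x` (coded allele, +1 or -1), one row per observed cell.
#' @export
observed_cells <- function(rm) {
  s <- Matrix::summary(rm$mat)
  data.frame(i = s$i, j = s$j, x = s$x)
}

#' Densify a read matrix
#' @param rm a [read_matrix]
#' @return a base numeric matrix with unobserved cells as exact zeros
#' @export
as_dense <- function(rm) {
  m <- as.matrix(rm$mat)
  dimnames(m) <- NULL
  m
}

# column/row degrees (number of observed entries)
.col_degrees <- function(rm) diff(rm$mat@p)
.row_degrees <- function(rm) tabulate(rm$mat@i + 1L, nbins = rm$n_reads)
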