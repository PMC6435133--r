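# Worked-example fixtures: the 10-SNP beta-2AR site map, the two true
# haplotypes, the 10 coded reads and their zero-filled read matrix, and
# the noiseless completed matrix whose rows are the parent haplotypes.

b2ar_map <- function() {
  site_map(chrom = "b2AR", pos = 1000L * (1:10),
           wild = c("G", "C", "G", "C", "T", "T", "T", "G", "C", "G"),
           rare = c("A", "A", "A", "G", "C", "C", "C", "A", "G", "A"))
}

b2ar_hm <- c(-1, 1, 1, -1, -1, -1, -1, 1, -1, 1)
b2ar_hp <- c(1, 1, -1, 1, 1, 1, 1, -1, 1, 1)
# parent of each of the 10 reads (1 = maternal pattern, 2 = paternal)
b2ar_parents <- c(1, 1, 1, 2, 2, 2, 1, 1, 2, 2)

b2ar_codewords <- function() {
  rbind(c(-1, 1, 1, 0, 0, 0, 0, 0, 0, 0),
        c(0, 0, 1, -1, -1, -1, 0, 0, 0, 0),
        c(0, 0, 1, -1, 0, 0, 0, 0, -1, 1),
        c(1, 1, -1, 1, 1, 1, 0, 0, 0, 0),
        c(0, 0, -1, 0, 0, 1, 1, -1, 1, 1),
        c(1, 1, 0, 0, 1, 1, 0, 0, 0, 0),
        c(-1, 1, 0, 0, -1, 0, 0, 0, 0, 1),
        c(-1, 1, 0, 0, -1, -1, -1, 0, 0, 0),
        c(1, 0, 0, 1, 0, 0, 1, -1, 1, 0),
        c(0, 0, -1, 1, 0, 0, 0, 0, 1, 1))
}

# the per-read nucleotides implied by the codewords and the site map
b2ar_nucleotide_reads <- function() {
  cw <- b2ar_codewords()
  map <- b2ar_map()
  lapply(seq_len(nrow(cw)), function(i) {
    sites <- which(cw[i, ] != 0)
    bases <- ifelse(cw[i, sites] > 0, map$wild[sites], map$rare[sites])
    list(id = paste0("r", i), sites = sites, bases = bases)
  })
}

b2ar_read_matrix <- function() read_matrix(b2ar_codewords())

# noiseless completed matrix: every read row replaced by its parent
b2ar_completed <- function() {
  do.call(rbind, lapply(b2ar_parents,
                        function(p) if (p == 1) b2ar_hm else b2ar_hp))
}

b2ar_truth <- function() haplotype_pair(b2ar_hm, b2ar_hp)

# ---- random-instance generators for property suites -------------------

# Small diploid instance with reads sampling random site subsets
# (uniform-like Omega).  Each read is required to cover at least one
# heterozygous and one homozygous truth site: a read seeing only-het (or
# only-hom) sites observes collinear restrictions of the two haplotypes
# and its row is under-determined by any rank-2 fit, so exact recovery
# would be ill-posed.  Coverage >= min_cov everywhere and a single
# connected block are also enforced.
gen_identifiable_instance <- function(l, n_reads, sizes, seed,
                                      het_fraction = 0.6, min_cov = 3L) {
  set.seed(seed)
  repeat {
    truth <- simulate_truth(l, all_het = FALSE, het_fraction = het_fraction)
    het <- truth$h1 != truth$h2
    if (!any(het) || all(het)) next
    frags <- vector("list", n_reads)
    parents <- integer(n_reads)
    ok <- TRUE
    for (k in seq_len(n_reads)) {
      found <- FALSE
      for (try in 1:60) {
        sz <- sample(sizes, 1)
        sites <- sort(sample.int(l, sz))
        if (length(unique(het[sites])) == 2) { found <- TRUE; break }
      }
      if (!found) { ok <- FALSE; break }
      p <- sample(1:2, 1)
      parents[k] <- p
      h <- if (p == 1) truth$h1 else truth$h2
      frags[[k]] <- fragment(paste0("r", k), sites, h[sites])
    }
    if (!ok) next
    rm <- build_read_matrix(frags, l)
    cov <- tabulate(observed_cells(rm)$j, nbins = l)
    if (any(cov < min_cov)) next
    if (length(partition_blocks(filter_informative(rm))) != 1L) next
    # relative phase only propagates through reads co-covering two
    # heterozygous sites, so the het-site graph must be one component
    # (homozygous sites are pinned individually) for the instance to be
    # identifiable
    rm_het <- read_matrix(rm$mat[, het, drop = FALSE])
    het_blocks <- partition_blocks(filter_informative(rm_het))
    if (length(het_blocks) != 1L ||
        length(attr(het_blocks, "missing_sites")) > 0L) next
    # every column must be observed by reads of BOTH parents: a
    # haplotype's allele at a column no read of its parent observes is
    # not determined by any rank-2 fit (an alternative exact completion
    # exists), so such instances are not identifiable
    obs <- observed_cells(rm)
    seen <- table(factor(parents[obs$i], 1:2), factor(obs$j, seq_len(l)))
    if (any(seen == 0)) next
    G <- do.call(rbind, lapply(parents,
                               function(p) if (p == 1) truth$h1 else truth$h2))
    return(list(truth = truth, rm = rm, generating = G, parents = parents))
  }
}

# flip one observed cell of a read matrix (for the brute-force oracle
# instances)
flip_one_cell <- function(rm, which_cell) {
  m <- rm$mat
  m@x[which_cell] <- -m@x[which_cell]
  read_matrix(m)
}

# ---- brute-force minimizer of the rank-2 fitting objective ------------

# Enumerates all haplotype pairs (h_a, h_b) over {+-1}^l and, for each,
# assigns every read row to its better-fitting haplotype; the objective
# is the total number of observed-cell mismatches (each mismatch of +-1
# entries contributes a squared error of 4, so mismatch count and
# squared error rank pairs identically).  Returns the minimum and the
# set of minimizing pairs.
mec_bruteforce <- function(rm) {
  l <- rm$n_sites
  M <- as_dense(rm)
  nobs_row <- rowSums(M != 0)
  H <- t(as.matrix(expand.grid(rep(list(c(-1, 1)), l))))  # l x 2^l
  agree <- M %*% H                       # sum over observed of r_ij h_j
  mism <- (nobs_row - agree) / 2         # per read x candidate mismatches
  best <- Inf; argmin <- list()
  n_h <- ncol(H)
  for (a in seq_len(n_h)) {
    objs <- colSums(pmin(mism[, a:n_h, drop = FALSE], mism[, a]))
    m <- min(objs)
    if (m < best) { best <- m; argmin <- list() }
    if (m <= best) {
      for (b in (a:n_h)[objs == best])
        argmin[[length(argmin) + 1L]] <- haplotype_pair(H[, a], H[, b])
    }
  }
  list(objective = best, pairs = argmin)
}

# objective of a concrete (possibly NA-containing) estimated pair under
# the same best-assignment rule; NA calls never match an observation
mec_objective <- function(rm, pair) {
  M <- as_dense(rm)
  obs <- observed_cells(rm)
  d_to <- function(h) {
    vapply(seq_len(rm$n_reads), function(i) {
      cells <- obs[obs$i == i, ]
      sum(is.na(h[cells$j]) | h[cells$j] != cells$x)
    }, numeric(1))
  }
  sum(pmin(d_to(pair$h1), d_to(pair$h2)))
}
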