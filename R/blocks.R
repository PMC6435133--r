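#' Drop uninformative reads
#'
#' Removes rows of the read matrix observing fewer than `min_snps` SNPs.
#' A read covering a single SNP carries no phase information (it cannot
#' link two sites), so the default threshold is 2.
#'
#' @param rm a [read_matrix]
#' @param min_snps minimum observed SNPs per retained read (>= 1)
#' @return a [read_matrix]; attribute `"removed_reads"` counts dropped rows
#' @export
filter_informative <- function(rm, min_snps = 2L) {
  stopifnot(min_snps >= 1L)
  deg <- .row_degrees(rm)
  keep <- deg >= min_snps
  out <- read_matrix(rm$mat[keep, , drop = FALSE])
  ids <- attr(rm, "read_ids")
  if (!is.null(ids)) attr(out, "read_ids") <- ids[keep]
  attr(out, "removed_reads") <- sum(!keep)
  out
}

#' Partition a read matrix into haplotype blocks
#'
#' Two SNPs can only be phased relative to each other if a chain of reads
#' links them; disconnected groups of SNPs have mutually arbitrary phase
#' and must be solved independently.  This computes the connected
#' components of the read-SNP graph (each read with >= 2 observed SNPs
#' connects the SNPs it covers) and returns one block per component.
#' SNPs covered by no informative read belong to no block and are listed
#' in the `"missing_sites"` attribute.
#'
#' @param rm a [read_matrix], ideally pre-filtered with
#'   [filter_informative()]
#' @return list of blocks sorted by first SNP index; each block is a list
#'   with `sites` (SNP columns, ascending), `reads` (member row indices)
#'   and `rm` (the sub-[read_matrix] over those rows and columns).
#'   Attribute `"missing_sites"` lists uncovered SNP columns.
#' @export
partition_blocks <- function(rm) {
  l <- rm$n_sites
  covered <- which(.col_degrees(rm) > 0L)
  if (!length(covered) || rm$n_reads == 0L) {
    out <- list()
    attr(out, "missing_sites") <- seq_len(l)
    return(out)
  }
  obs <- observed_cells(rm)
  obs <- obs[order(obs$i, obs$j), ]
  # chain consecutive sites of each multi-SNP read; enough for connectivity
  by_read <- split(obs$j, obs$i)
  edges <- do.call(rbind, lapply(by_read, function(js) {
    if (length(js) < 2L) return(NULL)
    cbind(js[-length(js)], js[-1L])
  }))
  g <- igraph::make_empty_graph(n = l, directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  # only SNPs linked to at least one other SNP form blocks; singleton
  # covered SNPs (only 1-SNP reads) are unphasable -> missing
  linked <- unique(as.vector(edges))
  blocks <- list()
  if (length(linked)) {
    read_rows <- as.integer(names(by_read))
    for (cid in unique(comp[linked])) {
      sites <- sort(which(comp == cid))
      sites <- intersect(sites, covered)
      member <- read_rows[vapply(by_read, function(js) js[1] %in% sites, logical(1))]
      sub <- read_matrix(rm$mat[member, sites, drop = FALSE])
      blocks[[length(blocks) + 1L]] <- list(sites = sites, reads = member, rm = sub)
    }
    blocks <- blocks[order(vapply(blocks, function(b) b$sites[1], numeric(1)))]
  }
  in_block <- unlist(lapply(blocks, `[[`, "sites"))
  attr(blocks, "missing_sites") <- setdiff(seq_len(l), in_block)
  blocks
}
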