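#' Assemble haplotypes end-to-end
#'
#' The full chain: drop uninformative reads, partition the read matrix
#' into haplotype blocks, complete each block with the chosen solver,
#' extract the block's haplotype pair, and stitch the per-block calls into
#' two full-length vectors (SNPs in no block stay `NA`; phase between
#' blocks is arbitrary).  A block whose solver fails is reported unphased
#' and the run continues.
#'
#' @param fragments list of [fragment] objects, or a path to a fragment
#'   file (hapcut dialect)
#' @param l haplotype length; defaults to the largest covered SNP index
#' @param solver `"optspace"` (default), `"svt"` or `"nuclear"`
#' @param rank 2 (general diploid) or 1 (all-heterozygous: second
#'   haplotype is the negative of the first)
#' @param all_het convenience flag forcing `rank = 1`
#' @param min_snps informative-read threshold for [filter_informative()]
#' @param zero_band missing band for [quantize_signs()]
#' @param consensus use cluster-majority extraction, see
#'   [extract_haplotypes()]
#' @param ... further arguments passed to the solver
#' @return object of class `hap_phasing`: list with `h1`, `h2`
#'   (full-length calls), `blocks` (each with `sites`, `pair`,
#'   `diagnostics`), `l`, `missing_sites`, `n_reads_used`,
#'   `n_reads_dropped`, `failed_blocks`
#' @export
hap_assemble <- function(fragments, l = NULL,
                         solver = c("optspace", "svt", "nuclear"),
                         rank = 2L, all_het = FALSE, min_snps = 2L,
                         zero_band = 0, consensus = FALSE, ...) {
  solver <- match.arg(solver)
  if (all_het) rank <- 1L
  if (is.character(fragments)) fragments <- parse_fragments(fragments)
  if (is.null(l)) {
    l <- if (length(fragments))
      max(vapply(fragments, function(f) max(f$sites), numeric(1))) else 0L
  }
  if (!length(fragments)) {
    warning("no fragments; returning an empty phasing")
    return(structure(list(h1 = rep(NA_real_, l), h2 = rep(NA_real_, l),
                          blocks = list(), l = l,
                          missing_sites = seq_len(l),
                          n_reads_used = 0L, n_reads_dropped = 0L,
                          failed_blocks = 0L, solver = solver),
                     class = "hap_phasing"))
  }
  rm_full <- build_read_matrix(fragments, l)
  assemble_read_matrix(rm_full, solver = solver, rank = rank,
                       min_snps = min_snps, zero_band = zero_band,
                       consensus = consensus, ...)
}

#' Assemble haplotypes from an already-built read matrix
#'
#' The matrix-level core of [hap_assemble()]: filter, partition into
#' blocks, complete and extract per block, stitch.
#'
#' @inheritParams hap_assemble
#' @param rm a [read_matrix]
#' @return a `hap_phasing`, see [hap_assemble()]
#' @export
assemble_read_matrix <- function(rm, solver = c("optspace", "svt", "nuclear"),
                                 rank = 2L, min_snps = 2L, zero_band = 0,
                                 consensus = FALSE, ...) {
  solver <- match.arg(solver)
  l <- rm$n_sites
  rm_f <- filter_informative(rm, min_snps = min_snps)
  blocks <- partition_blocks(rm_f)
  h1 <- rep(NA_real_, l); h2 <- rep(NA_real_, l)
  out_blocks <- list(); failed <- 0L
  for (b in blocks) {
    res <- tryCatch({
      H <- switch(solver,
                  optspace = complete_optspace(b$rm, r = rank, ...),
                  svt = complete_svt(b$rm, ...),
                  nuclear = complete_nuclear(b$rm, ...))
      pair <- extract_haplotypes(H, rank = rank, zero_band = zero_band,
                                 consensus = consensus)
      list(pair = pair, diagnostics = attr(H, "diagnostics"))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- failed + 1L
      pair <- haplotype_pair(rep(NA_real_, length(b$sites)),
                             rep(NA_real_, length(b$sites)))
      out_blocks[[length(out_blocks) + 1L]] <-
        list(sites = b$sites, pair = pair,
             diagnostics = list(failed = TRUE, message = conditionMessage(res)))
    } else {
      h1[b$sites] <- res$pair$h1
      h2[b$sites] <- res$pair$h2
      out_blocks[[length(out_blocks) + 1L]] <-
        list(sites = b$sites, pair = res$pair, diagnostics = res$diagnostics)
    }
  }
  structure(list(h1 = h1, h2 = h2, blocks = out_blocks, l = l,
                 missing_sites = attr(blocks, "missing_sites"),
                 n_reads_used = rm_f$n_reads,
                 n_reads_dropped = attr(rm_f, "removed_reads"),
                 failed_blocks = failed, solver = solver),
            class = "hap_phasing")
}

#' @export
print.hap_phasing <- function(x, ...) {
  cat(sprintf(paste0("<hap_phasing> solver=%s, l=%d, %d block(s), ",
                     "%d reads used (%d dropped), %d unphased SNP(s)\n"),
              x$solver, x$l, length(x$blocks), x$n_reads_used,
              x$n_reads_dropped, sum(is.na(x$h1) & is.na(x$h2))))
  invisible(x)
}

#' Evaluate a phasing against truth haplotypes
#'
#' Computes the full evaluation surface: reconstruction rate, switch
#' count/positions, switch error rate, short/long switch classification,
#' SNP missing rate, and block-length statistics (mean span and AN50,
#' in bp when a site map is given, else in SNPs).
#'
#' @param phasing a `hap_phasing` from [hap_assemble()], or any
#'   [haplotype_pair] (then `blocks` defaults to one whole-length block)
#' @param truth a [haplotype_pair]
#' @param map optional [site_map] for bp spans
#' @return object of class `hap_eval`: named list with `rr`, `switches`,
#'   `switch_positions`, `swer`, `short_switches`, `long_switches`, `smr`,
#'   `mean_block_span`, `an50`, `span_units`, `n_blocks`
#' @export
hap_evaluate <- function(phasing, truth, map = NULL) {
  if (inherits(phasing, "hap_phasing")) {
    est <- haplotype_pair(phasing$h1, phasing$h2)
    block_sites <- lapply(phasing$blocks, `[[`, "sites")
  } else {
    est <- phasing
    block_sites <- list(seq_along(est$h1))
  }
  l <- length(truth$h1)
  if (length(est$h1) != l) stop("estimate and truth lengths differ")
  rr <- reconstruction_rate(est, truth, block_sites)
  sw <- count_switches(est, truth, block_sites)
  cls <- classify_switches(est, truth, block_sites)
  spans <- vapply(block_sites, function(s) {
    if (!is.null(map)) map$pos[s[length(s)]] - map$pos[s[1]] + 1
    else s[length(s)] - s[1] + 1
  }, numeric(1))
  bs <- block_stats(spans, block_correctness(est, truth, block_sites))
  structure(list(rr = rr,
                 switches = sw$count, switch_positions = sw$positions,
                 swer = sw$count / l,
                 short_switches = cls$short, long_switches = cls$long,
                 smr = snp_missing_rate(est, l),
                 mean_block_span = bs$mean_span, an50 = bs$an50,
                 span_units = if (is.null(map)) "snps" else "bp",
                 n_blocks = length(block_sites)),
            class = "hap_eval")
}

#' @export
print.hap_eval <- function(x, ...) {
  cat("<hap_eval>\n")
  cat(sprintf("  reconstruction rate  %.4f\n", x$rr))
  cat(sprintf("  switches             %d (SWER %.4f; %d short, %d long)\n",
              x$switches, x$swer, x$short_switches, x$long_switches))
  cat(sprintf("  SNP missing rate     %.4f\n", x$smr))
  cat(sprintf("  blocks               %d (mean span %.1f %s, AN50 %s %s)\n",
              x$n_blocks, x$mean_block_span, x$span_units,
              format(x$an50), x$span_units))
  invisible(x)
}

#' Serialize an evaluation report as a TSV line set
#' @param ev a `hap_eval`
#' @param file path or connection
#' @export
write_eval_report <- function(ev, file) {
  keys <- c("rr", "switches", "swer", "short_switches", "long_switches",
            "smr", "mean_block_span", "an50", "span_units", "n_blocks")
  d <- data.frame(metric = keys,
                  value = vapply(keys, function(k) as.character(ev[[k]]),
                                 character(1)))
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
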